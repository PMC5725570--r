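# Synthetic single-cell cohort generator. Stands in for a multi-source
# single-cell study (blood plus two tumour indications) with known ground
# truth: cell labels, per-sample compositions and per-(type, source, patient)
# mean expression profiles.

# Leaf types simulated for a cell-type table (T subsets, not the parent).
leaf_types <- function(cell_types) cell_types$name

# Marker specification types: major types with T subsets collapsed to their
# parent, plus one spec per subset for the second classification stage.
marker_spec_types <- function(cell_types) {
  majors <- unique(ifelse(is.na(cell_types$parent), cell_types$name,
                          cell_types$parent))
  subsets <- cell_types$name[!is.na(cell_types$parent)]
  list(major = majors, subset = subsets)
}

# Pairs of types whose marker panels carry negative (NOT) criteria against
# each other, emulating closely related populations.
confusable_pairs <- function() {
  c("NK cell" = "T cell", "T cell" = "NK cell",
    "Macrophage" = "Dendritic cell", "Dendritic cell" = "Macrophage",
    "CAF" = "EC", "EC" = "CAF")
}

#' Generate per-(cell type, source) mean expression profiles
#'
#' Builds the mean log2 expression profile of every leaf cell type in every
#' tissue source, together with the marker specification and housekeeping
#' gene list implied by the configuration:
#'
#' * background genes share one baseline across types, perturbed by
#'   type-specific effects (T subtypes perturb one shared T-lineage profile);
#' * marker genes are expressed at `marker_level` in the types they mark and
#'   at zero elsewhere; NOT genes of a type are the AND markers of a
#'   designated confusable type;
#' * housekeeping genes have a single level shared by all types and sources;
#' * non-blood sources add per-gene Gaussian shifts (`source_shift_sd`) to
#'   background genes, modelling microenvironment-driven expression change.
#'
#' @param config a [cohort_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return Object of class `type_profiles`: per-source genes x leaf-type
#'   matrices plus marker specs, housekeeping and signature gene lists.
#' @export
generate_type_profiles <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  with_seed(seed, {
    ct <- config$cell_types
    leaves <- leaf_types(ct)
    spec_types <- marker_spec_types(ct)
    all_spec <- c(spec_types$major, spec_types$subset)

    n_hk <- round(config$hk_fraction * config$n_genes)
    n_marker <- round(config$marker_fraction * config$n_genes)
    per_type <- n_marker %/% length(all_spec)
    if (per_type < 2 || n_hk + n_marker >= config$n_genes)
      stopf("too few genes (%d) to allocate %d marker and %d housekeeping genes",
            config$n_genes, n_marker, n_hk)
    n_marker <- per_type * length(all_spec)
    n_bg <- config$n_genes - n_hk - n_marker

    gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
    marker_genes <- gene_ids[seq_len(n_marker)]
    hk_genes <- gene_ids[n_marker + seq_len(n_hk)]
    bg_genes <- gene_ids[(n_marker + n_hk) + seq_len(n_bg)]

    # marker panels: first half AND, rest OR
    panels <- split(marker_genes,
                    rep(all_spec, each = per_type))[all_spec]
    n_and <- ceiling(per_type / 2)
    spec_of <- function(tp) {
      and <- panels[[tp]][seq_len(n_and)]
      or <- setdiff(panels[[tp]], and)
      list(AND = and, OR = or, NOT = character())
    }
    mspec <- lapply(stats::setNames(all_spec, all_spec), spec_of)
    # negative criteria between confusable types
    conf <- confusable_pairs()
    for (tp in names(conf))
      if (tp %in% names(mspec) && conf[[tp]] %in% names(mspec))
        mspec[[tp]]$NOT <- mspec[[conf[[tp]]]]$AND
    for (s in spec_types$subset) {
      sibs <- setdiff(spec_types$subset, s)
      mspec[[s]]$NOT <- unlist(lapply(mspec[sibs], `[[`, "AND"),
                               use.names = FALSE)
    }

    # membership: which leaf types express a spec type's markers
    members <- lapply(stats::setNames(all_spec, all_spec), function(tp) {
      if (tp %in% ct$name) tp
      else ct$name[!is.na(ct$parent) & ct$parent == tp]
    })

    # baseline + type effects on background genes
    base <- pmax(0, stats::rnorm(n_bg, config$base_expression_scale, 2))
    hk_level <- pmax(0.5, stats::rnorm(n_hk, config$base_expression_scale + 1,
                                       0.5))
    parents <- unique(stats::na.omit(ct$parent))
    parent_eff <- lapply(stats::setNames(parents, parents), function(p)
      stats::rnorm(n_bg, 0, config$type_effect_sd))
    type_eff <- lapply(stats::setNames(leaves, leaves), function(t) {
      p <- ct$parent[ct$name == t]
      if (is.na(p)) stats::rnorm(n_bg, 0, config$type_effect_sd)
      else parent_eff[[p]] + stats::rnorm(n_bg, 0, config$subset_effect_sd)
    })

    base_profile <- matrix(0, config$n_genes, length(leaves),
                           dimnames = list(gene_ids, leaves))
    base_profile[hk_genes, ] <- hk_level
    for (t in leaves)
      base_profile[bg_genes, t] <- pmax(0, base + type_eff[[t]])
    for (tp in all_spec) {
      p <- mspec[[tp]]
      base_profile[c(p$AND, p$OR), members[[tp]]] <- config$marker_level
    }

    sources <- rownames(config$composition_alpha)
    profiles <- lapply(stats::setNames(sources, sources), function(s) {
      if (s == "blood" || config$source_shift_sd == 0) return(base_profile)
      shifted <- base_profile
      shifted[bg_genes, ] <- pmax(0, shifted[bg_genes, ] +
        matrix(stats::rnorm(n_bg * length(leaves), 0, config$source_shift_sd),
               n_bg, length(leaves)))
      shifted
    })

    # signature gene set: markers + most type-discriminating background genes
    n_extra <- max(0, config$n_signature_genes - n_marker)
    v <- apply(base_profile[bg_genes, , drop = FALSE], 1, stats::var)
    extra <- bg_genes[order(v, decreasing = TRUE)[seq_len(min(n_extra, n_bg))]]
    signature_genes <- c(marker_genes, extra)

    structure(
      list(profiles = profiles, gene_ids = gene_ids,
           marker_genes = marker_genes, hk_genes = hk_genes,
           bg_genes = bg_genes,
           marker_spec_major = mspec[spec_types$major],
           marker_spec_tsub = mspec[spec_types$subset],
           signature_genes = signature_genes,
           config = config),
      class = "type_profiles")
  })
}

#' Simulate one single-cell sample
#'
#' Draws cell labels multinomially from a composition vector and simulates
#' each cell as its (type, source) mean log2 profile (plus a patient effect
#' for malignant cells) with per-cell Gaussian noise, Bernoulli dropout, and
#' rescaling to TPM (each cell sums to 1e6). The recorded true composition is
#' the realized label frequency, not the multinomial parameter.
#'
#' @param profiles a `type_profiles` object (the source's matrix is
#'   selected), or directly a genes x types mean log2 profile matrix.
#' @param composition named fraction vector over cell types, summing to 1.
#'   Malignant types must be 0 for the blood source.
#' @param n_cells number of cells (0 gives an empty sample).
#' @param patient_id,source identifiers recorded in the annotation.
#' @param config a [cohort_config()] providing noise/dropout parameters.
#' @param patient_shift optional genes x types matrix of patient-specific
#'   additive log2 effects (typically malignant types only).
#' @param seed optional seed.
#' @return list with `expr` (genes x cells TPM matrix), `annotation`
#'   (cell_id, cell_type, patient, source) and `truth` (realized composition
#'   and per-cell labels).
#' @export
simulate_sample <- function(profiles, composition, n_cells, patient_id,
                            source, config, patient_shift = NULL,
                            seed = NULL) {
  P <- if (inherits(profiles, "type_profiles")) {
    if (!source %in% names(profiles$profiles))
      stopf("unknown source '%s'", source)
    profiles$profiles[[source]]
  } else profiles
  check_matrix(P, "profile matrix")
  types <- colnames(P)
  comp <- stats::setNames(numeric(length(types)), types)
  if (is.null(names(composition)))
    stopf("composition must be named by cell type")
  unknown <- setdiff(names(composition), types)
  if (length(unknown)) stopf("composition names not in profiles: %s",
                             paste(unknown, collapse = ", "))
  comp[names(composition)] <- composition
  if (abs(sum(comp) - 1) > 1e-6) stopf("composition must sum to 1")
  if (source == "blood" && inherits(profiles, "type_profiles")) {
    mal <- config$cell_types$name[config$cell_types$is_malignant]
    if (any(comp[intersect(mal, types)] > 0))
      stopf("malignant fractions must be 0 for the blood source")
  }
  if (!is.null(patient_shift)) {
    P2 <- P
    ov <- intersect(colnames(patient_shift), types)
    P2[, ov] <- pmax(0, P[, ov, drop = FALSE] +
                       patient_shift[rownames(P), ov, drop = FALSE])
    P <- P2
  }

  with_seed(seed, {
    if (n_cells == 0) {
      empty <- matrix(numeric(), nrow(P), 0,
                      dimnames = list(rownames(P), character()))
      expr_scale(empty) <- "TPM"
      return(list(expr = empty,
                  annotation = data.frame(cell_id = character(),
                                          cell_type = character(),
                                          patient = character(),
                                          source = character()),
                  truth = list(composition = comp * 0,
                               labels = character())))
    }
    labels <- sample(types, n_cells, replace = TRUE, prob = comp)
    Y <- P[, labels, drop = FALSE]
    if (config$noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(length(Y), 0, config$noise_sd),
                      nrow(Y), ncol(Y))
    Y <- pmax(Y, 0)
    if (config$dropout_rate > 0) {
      mid <- if (is.null(config$dropout_midpoint)) 2 else
        config$dropout_midpoint
      p_drop <- config$dropout_rate * stats::plogis(mid - Y)
      Y[matrix(stats::runif(length(Y)) < p_drop, nrow(Y), ncol(Y))] <- 0
    }
    expr <- rescale_tpm(pmax(2^Y - 1, 0))
    colnames(expr) <- sprintf("%s_c%04d", patient_id, seq_len(n_cells))
    realized <- stats::setNames(as.numeric(table(factor(labels, types))) /
                                  n_cells, types)
    list(expr = expr,
         annotation = data.frame(cell_id = colnames(expr),
                                 cell_type = labels,
                                 patient = patient_id, source = source,
                                 stringsAsFactors = FALSE),
         truth = list(composition = realized, labels = labels))
  })
}

#' Simulate a full multi-source single-cell cohort
#'
#' Generates type profiles, draws each sample's composition from the
#' source-specific Dirichlet prior, adds patient-specific effects to
#' malignant profiles, and simulates every sample. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return Object of class `sc_cohort`: per-sample expression/annotation/
#'   truth, a sample table, the realized composition matrix (ground truth),
#'   the `type_profiles` object, patient-specific malignant profiles, marker
#'   specs, and housekeeping/signature gene lists.
#' @export
simulate_cohort <- function(config) {
  profiles <- generate_type_profiles(config)
  ct <- config$cell_types
  mal_types <- ct$name[ct$is_malignant]
  bg <- profiles$bg_genes

  with_seed(config$seed + 1L, {
    samples <- list()
    info <- list()
    patient_profiles <- list()
    for (s in rownames(config$composition_alpha)) {
      for (j in seq_len(config$n_patients_per_source[[s]])) {
        pid <- sprintf("%s_P%02d", s, j)
        comp <- rdirichlet1(config$composition_alpha[s, ])
        shift <- NULL
        active_mal <- mal_types[comp[mal_types] > 0]
        if (length(active_mal) && config$patient_shift_sd > 0) {
          shift <- matrix(0, config$n_genes, length(active_mal),
                          dimnames = list(profiles$gene_ids, active_mal))
          shift[bg, ] <- stats::rnorm(length(bg) * length(active_mal), 0,
                                      config$patient_shift_sd)
        }
        smp <- simulate_sample(profiles, comp, config$cells_per_sample,
                               pid, s, config, patient_shift = shift)
        samples[[pid]] <- smp
        info[[pid]] <- data.frame(sample_id = pid, patient = pid, source = s,
                                  n_cells = ncol(smp$expr),
                                  stringsAsFactors = FALSE)
        if (length(active_mal)) {
          pp <- profiles$profiles[[s]][, active_mal, drop = FALSE]
          if (!is.null(shift)) pp <- pmax(0, pp + shift)
          patient_profiles[[pid]] <- pp
        }
      }
    }
    truth <- do.call(rbind, lapply(samples, function(x) x$truth$composition))
    rownames(truth) <- names(samples)
    structure(
      list(samples = samples,
           sample_info = do.call(rbind, c(info, make.row.names = FALSE)),
           truth_composition = truth,
           profiles = profiles,
           patient_malignant_profiles = patient_profiles,
           marker_spec_major = profiles$marker_spec_major,
           marker_spec_tsub = profiles$marker_spec_tsub,
           hk_genes = profiles$hk_genes,
           signature_genes = profiles$signature_genes,
           config = config),
      class = "sc_cohort")
  })
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic single-cell cohort: %d samples, %d genes, %d cells\n",
              length(x$samples), x$config$n_genes,
              sum(x$sample_info$n_cells)))
  print(table(x$sample_info$source))
  invisible(x)
}

#' Simulate a cohort with controlled tumour content
#'
#' Generates samples of one tumour source whose malignant fraction is fixed
#' at prescribed values (the non-malignant remainder is split in proportion
#' to the source's Dirichlet concentrations), for studying how estimation
#' quality depends on tumour content.
#'
#' @param config a [cohort_config()].
#' @param fractions tumour-cell fractions, one sample per value per patient.
#' @param source tumour source to simulate.
#' @param patients_per_fraction patients (with independent malignant
#'   profiles) per fraction.
#' @return An `sc_cohort` whose samples have the requested tumour content.
#' @export
simulate_content_sweep <- function(config, fractions = seq(0.1, 0.9, 0.1),
                                   source = "tumorA",
                                   patients_per_fraction = 1) {
  validate_cohort_config(config)
  profiles <- generate_type_profiles(config)
  ct <- config$cell_types
  alpha <- config$composition_alpha[source, ]
  mal <- ct$name[ct$is_malignant & alpha > 0]
  if (length(mal) != 1)
    stopf("source '%s' must carry exactly one malignant type", source)
  rest <- alpha
  rest[ct$name[ct$is_malignant]] <- 0
  rest <- rest / sum(rest)
  bg <- profiles$bg_genes

  with_seed(config$seed + 2L, {
    samples <- list(); info <- list(); patient_profiles <- list()
    k <- 0
    for (f in fractions) {
      for (j in seq_len(patients_per_fraction)) {
        k <- k + 1
        pid <- sprintf("%s_F%03d_P%02d", source, round(100 * f), j)
        comp <- rest * (1 - f)
        comp[mal] <- f
        shift <- NULL
        if (config$patient_shift_sd > 0) {
          shift <- matrix(0, config$n_genes, 1,
                          dimnames = list(profiles$gene_ids, mal))
          shift[bg, ] <- stats::rnorm(length(bg), 0, config$patient_shift_sd)
        }
        smp <- simulate_sample(profiles, comp, config$cells_per_sample,
                               pid, source, config, patient_shift = shift)
        samples[[pid]] <- smp
        info[[pid]] <- data.frame(sample_id = pid, patient = pid,
                                  source = source,
                                  n_cells = ncol(smp$expr),
                                  stringsAsFactors = FALSE)
        pp <- profiles$profiles[[source]][, mal, drop = FALSE]
        if (!is.null(shift)) pp <- pmax(0, pp + shift)
        patient_profiles[[pid]] <- pp
      }
    }
    truth <- do.call(rbind, lapply(samples, function(x) x$truth$composition))
    rownames(truth) <- names(samples)
    structure(
      list(samples = samples,
           sample_info = do.call(rbind, c(info, make.row.names = FALSE)),
           truth_composition = truth, profiles = profiles,
           patient_malignant_profiles = patient_profiles,
           marker_spec_major = profiles$marker_spec_major,
           marker_spec_tsub = profiles$marker_spec_tsub,
           hk_genes = profiles$hk_genes,
           signature_genes = profiles$signature_genes,
           config = config),
      class = "sc_cohort")
  })
}

#' Combined expression matrix and annotation of a cohort
#'
#' Binds all samples of a cohort into one genes x cells TPM matrix and one
#' annotation table (the form consumed by classification and
#' reference-profile construction).
#'
#' @param cohort an `sc_cohort`.
#' @return list with `expr` (TPM matrix) and `annotation` (data.frame).
#' @export
cohort_expression <- function(cohort) {
  expr <- do.call(cbind, lapply(cohort$samples, `[[`, "expr"))
  expr_scale(expr) <- "TPM"
  ann <- do.call(rbind, c(lapply(cohort$samples, `[[`, "annotation"),
                          make.row.names = FALSE))
  list(expr = expr, annotation = ann)
}
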