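#' Default per-class trait effect table for the synthetic cohort
#'
#' Target mean trait levels (percent of the within-class total) per FAB
#' class, emulating the contrasts seen across myeloid leukemia subtypes:
#' elevated paucimannose, hybrid and (s)Lewis x/a in the monocytic classes
#' (M4/M5), elevated bisection, antennarity, sialylation, core 1 and
#' alpha-2,8 sialylation in the erythroid class (M6), strong phosphorylation
#' and bisection with low paucimannose in M3, strong O-glycan sialyl-Lewis
#' x/a in the single megakaryoblastic line (M7), and alpha-2,8 sialylation
#' absent from M2 and M3.  Glycan-type targets close to 100 percent within
#' each class.
#'
#' @return data frame with columns \code{fab}, \code{trait}, \code{target}.
#' @export
default_trait_effects <- function() {
  n_traits <- c("N_oligomannose", "N_paucimannose", "N_hybrid", "N_complex",
                "N_phosphorylation", "N_bisection", "N_sLex_a",
                "N_antennarity", "N_sialylation")
  o_traits <- c("O_core1", "O_core2", "O_T_antigen", "O_Lex_a", "O_sLex_a",
                "O_H_antigen", "O_sulfation", "O_LacNAc", "O_sia_a28",
                "O_sia_a26_core")
  n_tab <- rbind(
    M2 = c(50, 4,    3,   43,   5,    3,   1.2, 8,  30),
    M3 = c(58, 4.2,  2,   35.8, 12.1, 4.2, 0.8, 6,  26),
    M4 = c(46, 11,   6.8, 36.2, 5,    1,   1.8, 5,  18),
    M5 = c(44, 17.7, 5,   33.3, 7.3,  0.3, 3.0, 4,  15),
    M6 = c(40, 7,    2,   51,   3,    4.2, 0.9, 14, 44),
    M7 = c(52, 9,    3,   36,   4,    1.5, 2.8, 7,  28))
  o_tab <- rbind(
    M2 = c(42,   58,   3,   1,   3,    0.3, 2,   14, 0, 24),
    M3 = c(52,   48,   5,   0.8, 2,    1.2, 2,   9,  0, 28),
    M4 = c(46,   54,   3,   2,   5,    0.2, 2,   12, 2, 26),
    M5 = c(44,   56,   3.5, 3.9, 6,    0,   1.7, 12, 1, 22),
    M6 = c(62.2, 37.8, 6,   0.5, 1.1,  0.7, 2.9, 7,  4, 40),
    M7 = c(48,   52,   4,   2,   12.3, 0.3, 2,   10, 5, 26))
  colnames(n_tab) <- n_traits
  colnames(o_tab) <- o_traits
  long <- function(tab) {
    data.frame(fab = rep(rownames(tab), ncol(tab)),
               trait = rep(colnames(tab), each = nrow(tab)),
               target = as.vector(tab), stringsAsFactors = FALSE)
  }
  rbind(long(n_tab), long(o_tab))
}

#' Default gene panel with planted trait linkages
#'
#' Gene-trait linkage specification for the synthetic transcriptome:
#' glycosyltransferases (GSTs) and hematopoietic transcription factors
#' (TFs) whose expression is generated to correlate with a driving derived
#' trait at a planted target correlation, plus unlinked background genes
#' generated as pure noise (planted correlation 0).
#'
#' @return data frame with columns \code{gene}, \code{panel}
#'   (\code{"GST"}/\code{"TF"}), \code{trait} (\code{NA} for background
#'   genes) and \code{target_r}.
#' @export
default_gene_links <- function() {
  rbind(
    data.frame(gene = c("ST8SIA6", "ST6GALNAC1", "ST6GALNAC5", "ST3GAL1",
                        "FUT7", "FUT9", "FUT6", "FUT1"),
               panel = "GST",
               trait = c("O_sia_a28", "O_sia_a26_core", "O_sia_a26_core",
                         "N_sia_a23", "N_sLex_a", "O_sLex_a", "O_sLex_a",
                         "O_H_antigen"),
               target_r = c(0.96, 0.48, 0.52, 0.24, 0.38, 0.51, -0.54,
                            0.35),
               stringsAsFactors = FALSE),
    data.frame(gene = c("MGAT5", "MGAT4A", "MAN1A1", "MAN2A1", "ST6GAL1",
                        "GCNT3", "FUT3"),
               panel = "GST", trait = NA_character_, target_r = 0,
               stringsAsFactors = FALSE),
    data.frame(gene = c("TAL1", "GATA1", "GATA2", "GATA3", "SPI1", "CEBPA",
                        "CBFA2T3"),
               panel = "TF",
               trait = c("O_sia_a28", "O_sia_a28", "N_sLex_a", "N_sLex_a",
                         "O_sia_a28", "O_sia_a28", "N_sialylation"),
               target_r = c(0.91, 0.89, -0.44, -0.46, -0.65, -0.74, 0.45),
               stringsAsFactors = FALSE))
}

# baseline per-glycan weights (percent of class total) before class effects
.baseline_weights <- function(library) {
  w <- c(
    H3N2 = 3.0, H2N2F1 = 1.5, H3N2F1 = 4.0,
    H4N2 = 2.0, H5N2 = 8.0, H6N2 = 9.0, H7N2 = 8.0, H8N2 = 9.0,
    H9N2 = 14.0, H5N2P1 = 2.5, H6N2P1 = 1.5,
    H4N3 = 0.7, H6N3 = 0.6, H5N3S1 = 0.9, H4N3F1S1a = 0.7,
    H4N3F1S1b = 0.6,
    H3N4 = 0.8, H4N4 = 1.0, H5N4 = 1.5, H5N4F1 = 2.0, H5N4S1a = 2.0,
    H5N4S1b = 1.8, H5N4S2a = 3.0, H5N4S2b = 3.2, H5N4F1S1 = 2.5,
    H5N4F1S2 = 3.5, H5N4F2 = 0.7, H5N4F2S2 = 1.3, H5N5 = 1.0,
    H5N5F1S1 = 1.2, H6N5S3 = 3.0, H6N5F1S3 = 1.0, H7N6S2 = 1.5,
    H7N6S4 = 2.0, H7N6F1S4 = 1.0,
    H1N1 = 4.0, H1N1F1 = 0.5, H1N1S1a = 12.0, H1N1S1b = 6.0,
    H1N1S2a = 24.0, H1N1S2b = 3.5, H1N1S3 = 5.0,
    H2N2 = 2.0, H2N2S1 = 6.0, H2N2S2 = 18.0, H2N2S3 = 1.5,
    H2N2F1a = 1.5, H2N2F1b = 0.5, H2N2F1S1 = 3.0, H2N2Su1 = 2.0,
    H3N3S1 = 8.0, H3N3F1S2 = 2.5)
  missing <- setdiff(names(library), names(w))
  if (length(missing))
    stop("no baseline weight for glycan(s): ",
         paste(missing, collapse = ", "))
  w[names(library)]
}

#' Configure a synthetic glycomics + transcriptomics cohort
#'
#' The configuration fixes everything the generator needs: the seed, the
#' number of samples per FAB class, the glycan library, the per-class trait
#' effect table, the Dirichlet concentration controlling within-class
#' abundance noise, the missingness and QC-failure rates, the replicate
#' structure, and the gene panel with planted trait linkages.
#'
#' @param seed integer random seed (mandatory; all randomness flows from it).
#' @param n_per_class named integer vector, samples per FAB class; default
#'   \code{c(M2 = 3, M3 = 1, M4 = 4, M5 = 6, M6 = 6, M7 = 1)} (21 samples).
#' @param library glycan library; default [builtin_glycan_library()].
#' @param effects trait effect table as from [default_trait_effects()].
#' @param concentration Dirichlet concentration (> 0; larger means less
#'   within-class noise; default 200).
#' @param missing_rate probability that a quantified glycan is absent from
#'   a sample's quant table (default 0.02).
#' @param qc_fail_rate probability that a record is emitted with failing QC
#'   metrics (default 0.03).
#' @param gene_links gene panel with planted linkages, as from
#'   [default_gene_links()].
#' @param expr_mean,expr_sd location and scale of simulated log-expression
#'   (defaults 4 and 1).
#' @param n_replicates technical replicates for the designated replicate
#'   sample (default 3).
#' @param replicate_rsd_target multiplicative noise (standard deviation of
#'   log areas) across technical replicates; the default 0.07 is calibrated
#'   so that the average triplicate RSD of glycans above 1 percent
#'   fractional abundance comes out near 7.8 percent.
#' @return object of class \code{cohort_config} (a list).
#' @export
cohort_config <- function(seed,
                          n_per_class = c(M2 = 3, M3 = 1, M4 = 4, M5 = 6,
                                          M6 = 6, M7 = 1),
                          library = builtin_glycan_library(),
                          effects = default_trait_effects(),
                          concentration = 200,
                          missing_rate = 0.02,
                          qc_fail_rate = 0.03,
                          gene_links = default_gene_links(),
                          expr_mean = 4, expr_sd = 1,
                          n_replicates = 3L,
                          replicate_rsd_target = 0.07) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  if (concentration <= 0) stop("Dirichlet concentration must be > 0")
  if (!is.null(gene_links) && nrow(gene_links) &&
      any(abs(gene_links$target_r) >= 1, na.rm = TRUE))
    stop("target correlations must lie in (-1, 1)")
  if (missing_rate < 0 || missing_rate > 1 || qc_fail_rate < 0 ||
      qc_fail_rate > 1)
    stop("rates must lie in [0, 1]")
  if (is.null(names(n_per_class)) || any(n_per_class < 0))
    stop("n_per_class must be a named non-negative vector")
  structure(list(seed = as.integer(seed), n_per_class = n_per_class,
                 library = library, effects = effects,
                 concentration = concentration,
                 missing_rate = missing_rate, qc_fail_rate = qc_fail_rate,
                 gene_links = gene_links, expr_mean = expr_mean,
                 expr_sd = expr_sd, n_replicates = as.integer(n_replicates),
                 replicate_rsd_target = replicate_rsd_target),
            class = "cohort_config")
}

# Iterative proportional fitting of per-glycan weights toward trait targets
# within one glycan class.  Weights stay on the 0-100 scale (class total
# fixed at 100); each pass rescales trait members to the target and
# non-members to the complement.  Returns weights and achieved residuals.
.ipf_class_weights <- function(w, targets, members, max_iter = 300,
                               tol = 1e-8) {
  stopifnot(abs(sum(w) - 100) < 1e-6)
  for (k in seq_along(targets)) {
    m <- members[[k]]
    if (targets[k] > 0 && !any(w[m] > 0))
      stop("infeasible effect: trait '", names(targets)[k],
           "' has target ", targets[k],
           " but no member glycan with positive baseline weight")
    if (targets[k] > 100 || targets[k] < 0)
      stop("trait target out of [0, 100]: ", names(targets)[k])
  }
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_along(targets)) {
      m <- members[[k]]
      cur <- sum(w[m])
      tg <- targets[k]
      delta <- max(delta, abs(cur - tg))
      if (abs(cur - tg) < tol) next
      if (cur > 0 && cur < 100) {
        w[m] <- w[m] * tg / cur
        w[!m] <- w[!m] * (100 - tg) / (100 - cur)
      }
    }
    if (delta < tol) break
  }
  achieved <- vapply(members, function(m) sum(w[m]), numeric(1))
  list(weights = w, residuals = abs(achieved - targets))
}

# Per-class mean weight vectors (rows: classes, cols: glycans), by applying
# the effect table to the baseline via IPF separately for N and O glycans.
.class_weights <- function(config) {
  lib <- config$library
  base <- .baseline_weights(lib)
  cls <- vapply(lib, `[[`, character(1), "glycan_class")
  traits <- builtin_traits()
  fabs <- names(config$n_per_class)
  eff <- config$effects
  unknown <- setdiff(unique(eff$trait), names(traits))
  if (length(unknown))
    stop("effect table references unknown trait(s): ",
         paste(unknown, collapse = ", "))
  # closure check: glycan-type targets must sum to 100 within a class
  type_sets <- list(N = c("N_oligomannose", "N_paucimannose", "N_hybrid",
                          "N_complex"),
                    O = c("O_core1", "O_core2"))
  for (fab in fabs) for (k in names(type_sets)) {
    sel <- eff$fab == fab & eff$trait %in% type_sets[[k]]
    if (sum(sel) == length(type_sets[[k]]) &&
        abs(sum(eff$target[sel]) - 100) > 0.01)
      stop("infeasible effect table: ", k, "-glycan type targets for ",
           fab, " sum to ", sum(eff$target[sel]), ", not 100")
  }
  W <- matrix(rep(base, length(fabs)), nrow = length(fabs), byrow = TRUE,
              dimnames = list(fabs, names(lib)))
  residuals <- list()
  for (fab in fabs) {
    res_fab <- numeric(0)
    for (k in c("N", "O")) {
      in_class <- cls == k
      sel <- eff$fab == fab &
        vapply(eff$trait, function(tr) traits[[tr]]$glycan_class == k,
               logical(1))
      if (!any(sel)) next
      targets <- stats::setNames(eff$target[sel], eff$trait[sel])
      members <- lapply(eff$trait[sel], function(tr) {
        td <- traits[[tr]]
        vapply(lib, function(r)
          r$glycan_class == k && isTRUE(td$predicate(r)), logical(1))[in_class]
      })
      fit <- .ipf_class_weights(W[fab, in_class], targets, members)
      W[fab, in_class] <- fit$weights
      res_fab <- c(res_fab, fit$residuals)
    }
    residuals[[fab]] <- res_fab
  }
  max_res <- max(unlist(residuals), 0)
  if (max_res > 0.5)
    warning(sprintf("trait-effect fitting residual %.2f percentage points exceeds 0.5",
                    max_res))
  list(weights = W, residuals = residuals)
}

#' Simulate a FAB-structured glycomics + transcriptomics cohort
#'
#' Generates, from a fixed seed, (i) a long-format glycan quantification
#' table with peak areas and QC metrics (a configured fraction of records
#' failing the retention-time/isotope-dot-product/signal-to-noise criteria,
#' and a configured fraction missing), including technical replicates for
#' one designated sample; (ii) the glycan annotation table; (iii) a
#' samples-by-genes log-expression matrix in which each linked gene is
#' constructed to correlate with its driving derived trait at the planted
#' target correlation; (iv) sample metadata with FAB labels; and (v) the
#' ground truth needed to score recovery.
#'
#' Per sample, the glycan fractional-abundance vector is drawn from a
#' Dirichlet distribution (independently for N- and O-glycans) whose mean
#' is the class-specific weight vector obtained by iterative proportional
#' fitting of the trait effect table onto the baseline profile.  Expression
#' of a linked gene is \code{mean + sd * (r * z(trait) + sqrt(1 - r^2) *
#' noise)} over the cohort, so its population correlation with the realized
#' trait equals the planted \code{r}.
#'
#' @param config a \code{cohort_config}.
#' @return list with elements \code{quant} (data frame: sample, replicate,
#'   glycan, area, rt_match, idotp, snr), \code{annotation} (data frame),
#'   \code{expression} (matrix samples x genes), \code{metadata} (data
#'   frame: sample, fab), \code{truth} (list: \code{fab}, \code{planted},
#'   \code{class_weights}, \code{ipf_residuals}, \code{effects},
#'   \code{true_fractions}, \code{true_traits}, \code{missing_mask},
#'   \code{qc_fail_mask}, \code{replicate_sample}, \code{seed}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  lib <- config$library
  cls <- vapply(lib, `[[`, character(1), "glycan_class")
  glycans <- names(lib)
  cw <- .class_weights(config)
  fabs <- rep(names(config$n_per_class), config$n_per_class)
  samples <- unlist(lapply(names(config$n_per_class), function(f) {
    n <- config$n_per_class[[f]]
    if (n == 0) return(character(0))
    sprintf("%s_s%02d", f, seq_len(n))
  }))
  names(fabs) <- samples
  n <- length(samples)
  # true per-sample fractional abundances: Dirichlet per class
  frac <- matrix(0, n, length(glycans), dimnames = list(samples, glycans))
  for (i in seq_len(n)) {
    for (k in c("N", "O")) {
      cols <- which(cls == k)
      alpha <- config$concentration * cw$weights[fabs[i], cols] / 100
      pos <- alpha > 0
      draw <- numeric(length(cols))
      draw[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
      frac[i, cols] <- draw / sum(draw) * 100
    }
  }
  true_traits <- derive_traits(frac, lib)
  # designated replicate sample: first sample of the largest class
  rep_sample <- samples[which.max(fabs == names(which.max(config$n_per_class)))]
  # quant table
  rows <- list()
  missing_mask <- matrix(FALSE, n, length(glycans),
                         dimnames = dimnames(frac))
  qc_fail_mask <- matrix(FALSE, n, length(glycans),
                         dimnames = dimnames(frac))
  for (i in seq_len(n)) {
    s <- samples[i]
    n_reps <- if (s == rep_sample) config$n_replicates else 1L
    for (r in seq_len(n_reps)) {
      for (k in c("N", "O")) {
        cols <- which(cls == k)
        total_area <- stats::rlnorm(1, meanlog = log(1e9), sdlog = 0.3)
        noise <- exp(stats::rnorm(length(cols), 0,
                                  config$replicate_rsd_target))
        areas <- frac[i, cols] / 100 * total_area * noise
        present <- frac[i, cols] > 0
        # missingness and QC failure are sample-level events injected into
        # the primary replicate; technical re-injections are emitted clean
        if (r == 1L) {
          miss <- stats::runif(length(cols)) < config$missing_rate
          fail <- stats::runif(length(cols)) < config$qc_fail_rate
          missing_mask[i, cols] <- miss
          qc_fail_mask[i, cols] <- fail & !miss
        } else {
          miss <- rep(FALSE, length(cols))
          fail <- rep(FALSE, length(cols))
        }
        keep <- present & !miss
        if (!any(keep)) next
        m <- sum(keep)
        idotp <- stats::runif(m, 0.90, 1.0)
        snr <- 10^stats::runif(m, 1, 2.3)
        rt <- rep(TRUE, m)
        fk <- fail[keep]
        if (any(fk)) {
          mode <- sample(c("idotp", "snr", "rt"), sum(fk), replace = TRUE)
          idotp[fk][mode == "idotp"] <-
            stats::runif(sum(mode == "idotp"), 0.5, 0.849)
          snr[fk][mode == "snr"] <- stats::runif(sum(mode == "snr"), 0, 5.9)
          rt[fk][mode == "rt"] <- FALSE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, replicate = sprintf("r%d", r),
          glycan = glycans[cols][keep], area = areas[keep],
          rt_match = rt, idotp = idotp, snr = snr,
          stringsAsFactors = FALSE)
      }
    }
  }
  quant <- do.call(rbind, rows)
  rownames(quant) <- NULL
  # expression with planted trait linkages
  links <- config$gene_links
  genes <- links$gene
  expr <- matrix(NA_real_, n, length(genes),
                 dimnames = list(samples, genes))
  for (g in seq_along(genes)) {
    eps <- stats::rnorm(n)
    tr <- links$trait[g]
    r <- links$target_r[g]
    if (is.na(tr) || r == 0) {
      expr[, g] <- config$expr_mean + config$expr_sd * eps
    } else {
      tv <- true_traits[, tr]
      sdt <- stats::sd(tv)
      if (is.na(sdt) || sdt == 0) {
        warning("driving trait ", tr, " is constant; gene ", genes[g],
                " generated as noise")
        expr[, g] <- config$expr_mean + config$expr_sd * eps
      } else {
        z <- (tv - mean(tv)) / sdt
        expr[, g] <- config$expr_mean +
          config$expr_sd * (r * z + sqrt(1 - r^2) * eps)
      }
    }
  }
  truth <- list(fab = fabs, planted = links, class_weights = cw$weights,
                ipf_residuals = cw$residuals, effects = config$effects,
                true_fractions = frac, true_traits = true_traits,
                missing_mask = missing_mask, qc_fail_mask = qc_fail_mask,
                replicate_sample = rep_sample, seed = config$seed)
  list(quant = quant, annotation = library_as_data_frame(lib),
       expression = expr,
       metadata = data.frame(sample = samples, fab = unname(fabs),
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Mean silhouette width of a labelled embedding
#'
#' Computes the mean silhouette width of samples in a (score) matrix under
#' Euclidean distance, given group labels.  Samples in singleton groups
#' contribute a width of zero, following the usual convention.
#'
#' @param x numeric matrix, samples in rows (e.g. the first two PCA score
#'   dimensions).
#' @param labels group label per sample.
#' @return mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(x, labels) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(x))
  widths <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

#' Score recovery of the planted ground truth
#'
#' Compares pipeline outputs against the generator's ground truth:
#' sign agreement and absolute error of estimated versus planted gene-trait
#' correlations, the FAB class-separation of the PCA score plot (mean
#' silhouette on the first two score dimensions), and, when a trait matrix
#' is supplied, the per-class error between observed trait means and the
#' planted targets.
#'
#' @param truth the \code{truth} element of [simulate_cohort()].
#' @param cor_table output of [correlate_traits_genes()] containing the
#'   planted (trait, gene) pairs.
#' @param pca a \code{glyco_pca} fitted on the cohort (or a score matrix).
#' @param traits optional trait matrix (samples x traits) from the
#'   pipeline, for trait-mean recovery.
#' @param rcca optional \code{glyco_rcca} whose cross-block similarity
#'   contains the planted (trait, gene) cells; scores the fraction of
#'   planted nonzero links whose similarity entry has the planted sign.
#' @return list with \code{correlation} (data frame: gene, trait, planted,
#'   estimated, abs_error, sign_match), \code{sign_recovery} (fraction of
#'   planted nonzero links with matching sign), \code{mean_abs_error},
#'   \code{silhouette}, \code{similarity_sign_recovery}, and
#'   \code{trait_mean_error} (data frame or \code{NULL}).
#' @export
score_recovery <- function(truth, cor_table = NULL, pca = NULL,
                           traits = NULL, rcca = NULL) {
  out <- list()
  if (!is.null(cor_table)) {
    planted <- truth$planted[!is.na(truth$planted$trait) &
                               truth$planted$target_r != 0, ]
    est <- merge(planted, cor_table, by = c("gene", "trait"))
    out$correlation <- data.frame(
      gene = est$gene, trait = est$trait, planted = est$target_r,
      estimated = est$r, abs_error = abs(est$r - est$target_r),
      sign_match = sign(est$r) == sign(est$target_r),
      stringsAsFactors = FALSE)
    out$sign_recovery <- mean(out$correlation$sign_match)
    out$mean_abs_error <- mean(out$correlation$abs_error)
  }
  if (!is.null(pca)) {
    scores <- if (inherits(pca, "glyco_pca")) pca$scores else pca
    scores <- scores[, 1:2, drop = FALSE]
    out$silhouette <- silhouette_score(scores, truth$fab[rownames(scores)])
  }
  if (!is.null(rcca)) {
    sim <- if (inherits(rcca, "glyco_rcca")) rcca$similarity else rcca
    planted <- truth$planted[!is.na(truth$planted$trait) &
                               truth$planted$target_r != 0, ]
    planted <- planted[planted$trait %in% rownames(sim) &
                         planted$gene %in% colnames(sim), ]
    if (nrow(planted)) {
      got <- sim[cbind(planted$trait, planted$gene)]
      out$similarity_sign_recovery <-
        mean(sign(got) == sign(planted$target_r))
    }
  }
  if (!is.null(traits)) {
    obs <- fab_group_summary(traits,
                             truth$fab[rownames(traits)])
    eff <- truth$effects
    eff <- eff[eff$trait %in% colnames(obs) & eff$fab %in% rownames(obs), ]
    eff$observed <- obs[cbind(eff$fab, eff$trait)]
    eff$abs_error <- abs(eff$observed - eff$target)
    out$trait_mean_error <- eff
  }
  out
}
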