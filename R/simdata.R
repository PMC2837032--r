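#' Configuration for the two-library count simulator
#'
#' Defaults emulate the statistical structure of a two-library EST/tag
#' sporulation transcriptome survey: ~13,169 contigs sharing 125,456
#' (library D) and 99,632 (library L) reads, a heavy-tailed log-normal
#' abundance distribution (most contigs at 1-5 hits, a few in the
#' hundreds), a minority of contigs with true fold changes in either
#' direction, and a GO vocabulary with one term planted so that it is
#' enriched among upregulated contigs.
#'
#' @param m Number of contigs (default 13169).
#' @param n_d,n_l Library totals (defaults 125456 and 99632).
#' @param pi_up,pi_down Fractions of contigs with a true fold change up /
#'   down in the L library (defaults 0.12 and 0.09; `pi_up + pi_down <= 1`).
#' @param log_fold_mean,log_fold_sd Natural-log fold-change magnitude
#'   distribution (folded normal, so magnitudes are positive); the fold
#'   applied to the L-side weight is `exp(+f)` for up and `exp(-f)` for
#'   down contigs.
#' @param abundance_log_mean,abundance_log_sd Log-normal baseline
#'   abundance parameters; the default sd 1.8 produces the observed
#'   heavy tail.
#' @param n_terms GO vocabulary size (default 50).
#' @param terms_per_contig_mean Expected number of terms per annotated
#'   contig (default 4).
#' @param planted_terms Named numeric vector mapping a GO id to its
#'   enrichment factor among upregulated contigs (default
#'   `c("GO:0008219" = 4)`, a "cell death" style planting).
#' @param annotated_fraction Fraction of contigs carrying an ortholog
#'   accession and GO terms (default 0.19).
#' @param de_min_expected Restrict true fold changes to contigs whose
#'   baseline expected hit count in library D is at least this (default
#'   0 = no restriction); used to construct well-expressed-signal
#'   configurations for power studies.
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(m = 13169, n_d = 125456, n_l = 99632,
                       pi_up = 0.12, pi_down = 0.09,
                       log_fold_mean = 1, log_fold_sd = 0.5,
                       abundance_log_mean = 0, abundance_log_sd = 1.8,
                       n_terms = 50, terms_per_contig_mean = 4,
                       planted_terms = c("GO:0008219" = 4),
                       annotated_fraction = 0.19,
                       de_min_expected = 0, seed = 1L) {
  cfg <- list(m = as.integer(m), n_d = as.integer(n_d), n_l = as.integer(n_l),
              pi_up = pi_up, pi_down = pi_down,
              log_fold_mean = log_fold_mean, log_fold_sd = log_fold_sd,
              abundance_log_mean = abundance_log_mean,
              abundance_log_sd = abundance_log_sd,
              n_terms = as.integer(n_terms),
              terms_per_contig_mean = terms_per_contig_mean,
              planted_terms = planted_terms,
              annotated_fraction = annotated_fraction,
              de_min_expected = de_min_expected, seed = as.integer(seed))
  with(cfg, {
    stopifnot(m >= 1, n_d >= 1, n_l >= 1,
              pi_up >= 0, pi_down >= 0, pi_up + pi_down <= 1,
              log_fold_sd > 0, abundance_log_sd > 0,
              n_terms >= 1, terms_per_contig_mean > 0,
              annotated_fraction >= 0, annotated_fraction <= 1,
              de_min_expected >= 0)
  })
  base_q <- cfg$terms_per_contig_mean / cfg$n_terms
  if (length(cfg$planted_terms)) {
    if (is.null(names(cfg$planted_terms)) ||
        any(!grepl("^GO:\\d{7}$", names(cfg$planted_terms))))
      stop("planted_terms must be a named vector with GO:NNNNNNN names")
    if (any(base_q * cfg$planted_terms > 1))
      stop("infeasible config: planted term assignment probability ",
           "(base rate x enrichment factor) exceeds 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-library count experiment with planted truth
#'
#' Draws baseline contig weights from a log-normal distribution
#' (normalised to sum 1), applies planted fold changes to the L-side
#' weights (renormalised), and samples the two libraries as multinomials
#' conditioned on the exact library totals — matching the conditioning
#' of the Audic-Claverie test. GO annotations are assigned
#' per-contig-per-term with the configured base rate, multiplied by the
#' planted enrichment factor for upregulated contigs. All draws come
#' from a single seeded RNG stream in a fixed order (weights, DE
#' assignment, folds, counts D, counts L, annotation flags, term
#' assignments), so output is fully reproducible; the caller's RNG state
#' is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `counts` (a [count_table()]),
#'   `annotations` (annotation data frame as from
#'   [read_annotation_table()]) and `truth` (data frame `contig_id`,
#'   `baseline_weight`, `fold`, `is_de` in `{"up","down","null"}`,
#'   `planted_terms_held` list-column).
#' @export
simulate_libraries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  m <- config$m
  ids <- sprintf("contig%05d", seq_len(m))

  w <- stats::rlnorm(m, config$abundance_log_mean, config$abundance_log_sd)
  w <- w / sum(w)

  eligible <- which(w * config$n_d >= config$de_min_expected)
  n_up <- round(config$pi_up * m); n_down <- round(config$pi_down * m)
  if (length(eligible) < n_up + n_down)
    stop("infeasible config: fewer eligible contigs (baseline expected ",
         "hits >= de_min_expected) than requested DE contigs")
  de_idx <- sample(eligible, n_up + n_down)
  is_de <- rep("null", m)
  is_de[de_idx[seq_len(n_up)]] <- "up"
  is_de[de_idx[seq_len(n_down) + n_up]] <- "down"

  fmag <- abs(stats::rnorm(m, config$log_fold_mean, config$log_fold_sd))
  fold <- rep(1, m)
  fold[is_de == "up"] <- exp(fmag[is_de == "up"])
  fold[is_de == "down"] <- exp(-fmag[is_de == "down"])

  w_l <- w * fold
  w_l <- w_l / sum(w_l)

  hits_d <- as.integer(stats::rmultinom(1, config$n_d, w))
  hits_l <- as.integer(stats::rmultinom(1, config$n_l, w_l))

  annotated <- stats::runif(m) < config$annotated_fraction
  base_q <- config$terms_per_contig_mean / config$n_terms
  planted <- names(config$planted_terms)
  decoys <- setdiff(sprintf("GO:%07d", 1000000 + seq_len(config$n_terms + length(planted))),
                    planted)[seq_len(config$n_terms - length(planted))]
  vocab <- c(planted, decoys)
  qmat_base <- rep(base_q, length(vocab))
  go_terms <- vector("list", m)
  for (i in seq_len(m)) {
    if (!annotated[i]) { go_terms[[i]] <- character(0); next }
    q <- qmat_base
    if (length(planted) && is_de[i] == "up")
      q[seq_along(planted)] <- pmin(1, base_q * config$planted_terms)
    go_terms[[i]] <- vocab[stats::runif(length(vocab)) < q]
  }

  annotations <- data.frame(
    contig_id = ids,
    accession = ifelse(annotated, sprintf("ACC%05d", seq_len(m)), ""),
    description = ifelse(annotated, sprintf("simulated ortholog %d", seq_len(m)), ""),
    ko_id = "", stringsAsFactors = FALSE)
  annotations$go_terms <- go_terms
  annotations <- annotations[annotated, , drop = FALSE]
  rownames(annotations) <- NULL

  truth <- data.frame(contig_id = ids, baseline_weight = w, fold = fold,
                      is_de = is_de, stringsAsFactors = FALSE)
  truth$planted_terms_held <- lapply(go_terms, intersect, x = planted)

  list(counts = count_table(data.frame(contig_id = ids, hits_d = hits_d,
                                       hits_l = hits_l,
                                       stringsAsFactors = FALSE)),
       annotations = annotations, truth = truth)
}

#' Recovery of planted differential expression
#'
#' Compares test calls against simulated ground truth.
#'
#' @param de An `ac_de` table computed on a [simulate_libraries()]
#'   output.
#' @param truth The matching `truth` data frame.
#' @param alpha Significance threshold.
#' @return List with `power` (significant among true-DE contigs;
#'   `NA` with `power_defined = FALSE` when there is no true DE),
#'   `empirical_fdr` (true-null among significant calls; 0 with
#'   `fdr_defined = FALSE` when nothing is significant),
#'   `direction_accuracy` (correct direction among significant true-DE
#'   calls; `NA` with flag when there are none), and the raw tallies.
#' @export
evaluate_recovery <- function(de, truth, alpha = 0.05) {
  stopifnot(nrow(de) == nrow(truth))
  de <- classify_de(de, alpha)
  ord <- match(truth$contig_id, de$contig_id)
  stopifnot(!any(is.na(ord)))
  de <- de[ord, ]
  true_de <- truth$is_de != "null"
  sig <- de$significant
  n_sig <- sum(sig)
  power_defined <- any(true_de)
  fdr_defined <- n_sig > 0
  hit <- sig & true_de
  out <- list(
    power = if (power_defined) sum(hit) / sum(true_de) else NA_real_,
    power_defined = power_defined,
    empirical_fdr = if (fdr_defined) sum(sig & !true_de) / n_sig else 0,
    fdr_defined = fdr_defined,
    n_true_de = sum(true_de), n_significant = n_sig,
    n_true_positive = sum(hit))
  out$direction_accuracy <-
    if (any(hit)) mean(de$direction[hit] == truth$is_de[hit]) else NA_real_
  out$direction_defined <- any(hit)
  out
}
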