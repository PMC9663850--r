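# Delta/alpha-ratio scoring per sleep state and K-means stratification
# of injured subjects into high-delta (SBI-HD) and low-delta (SBI-LD)
# cohorts. The delta/alpha ratio is the injury-severity biomarker: a
# persistently high ratio marks the worse outcome trajectory.

#' Per-state delta/alpha scores
#'
#' For each state (NREM, REM, AWAKE), the ratio of mean delta power to
#' mean alpha power over that state's epochs, computed on a post-injury
#' record and normalized by the same statistic on the subject's baseline
#' record (rel.un.: 1.0 means unchanged from baseline). A state absent
#' from either record yields `NA` for that score.
#'
#' @param bp,h Post-injury `band_power_table` and [hypnogram()].
#' @param bp_base,h_base Baseline record, same subject.
#' @param subject_id,day_index Identifiers carried into the output.
#' @return One-row data frame with raw ratios (`raw_*`) and normalized
#'   scores (`score_NREM`, `score_REM`, `score_AWAKE`).
#' @export
delta_alpha_scores <- function(bp, h, bp_base, h_base,
                               subject_id = NA_character_,
                               day_index = NA_integer_) {
  stopifnot(inherits(h, "hypnogram"), inherits(h_base, "hypnogram"))
  ratio <- function(bp, h, state) {
    sel <- h$labels[seq_len(nrow(bp))] == state
    d <- mean(bp$delta[sel], na.rm = TRUE)
    a <- mean(bp$alpha[sel], na.rm = TRUE)
    if (!any(sel, na.rm = TRUE) || !is.finite(d) || !is.finite(a) || a == 0)
      return(NA_real_)
    d / a
  }
  states <- c("NREM", "REM", "AWAKE")
  raw <- vapply(states, function(s) ratio(bp, h, s), numeric(1))
  base <- vapply(states, function(s) ratio(bp_base, h_base, s), numeric(1))
  score <- raw / base
  out <- data.frame(subject_id = subject_id, day_index = day_index,
                    raw_NREM = raw[1], raw_REM = raw[2], raw_AWAKE = raw[3],
                    score_NREM = score[1], score_REM = score[2],
                    score_AWAKE = score[3])
  rownames(out) <- NULL
  out
}

#' Stratify injured subjects by K-means on delta/alpha scores
#'
#' K-means with k = 2 on the three-dimensional normalized scores
#' (NREM, REM, AWAKE) of all subjects, controls included, with 50
#' seeded random restarts (best within-cluster sum of squares kept).
#' Injured subjects falling in the cluster that contains the majority of
#' controls are labeled `SBI-LD`, the rest `SBI-HD`; controls are always
#' labeled `CONTROL`. A control-majority tie is broken by taking the
#' cluster with the smaller mean score as the LD side. If all score
#' vectors are identical the clustering is degenerate: a warning is
#' raised and every injured subject is labeled `SBI-LD`.
#'
#' @param scores Data frame with `subject_id`, `score_NREM`,
#'   `score_REM`, `score_AWAKE` (one row per subject). Rows with missing
#'   scores are dropped with a warning.
#' @param group_of Named character vector mapping `subject_id` to
#'   `"control"` or `"injured"`.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (default 50).
#' @return Data frame `subject_id`, `label`, plus the three scores; the
#'   2 x 3 cluster `centroids`, the centroid `separation` (Euclidean
#'   distance) and `plot_radius` (90% of it, the construct used to draw
#'   the control/LD cluster circle) are attached as attributes.
#' @export
stratify_kmeans <- function(scores, group_of, seed = 1, nstart = 50) {
  cols <- c("score_NREM", "score_REM", "score_AWAKE")
  stopifnot(all(c("subject_id", cols) %in% names(scores)))
  ok <- stats::complete.cases(scores[cols])
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " subject(s) with missing state scores")
    scores <- scores[ok, , drop = FALSE]
  }
  grp <- group_of[scores$subject_id]
  if (anyNA(grp)) stop("stratify_kmeans: ungrouped subject(s)")
  if (sum(grp == "injured") < 2)
    stop("stratify_kmeans: need at least two injured subjects")
  X <- as.matrix(scores[cols])
  label <- ifelse(grp == "control", "CONTROL", "SBI-LD")
  degenerate <- nrow(unique(X)) < 2
  if (degenerate) {
    warning("stratify_kmeans: all score vectors identical; ",
            "labeling every injured subject SBI-LD")
    centroids <- rbind(X[1, ], X[1, ])
  } else {
    set.seed(seed)
    km <- stats::kmeans(X, centers = 2, nstart = nstart)
    ctrl_tab <- tabulate(km$cluster[grp == "control"], nbins = 2)
    ld_cluster <- if (ctrl_tab[1] != ctrl_tab[2]) which.max(ctrl_tab) else
      which.min(rowMeans(km$centers))
    label[grp == "injured" & km$cluster != ld_cluster] <- "SBI-HD"
    centroids <- km$centers
  }
  out <- data.frame(subject_id = scores$subject_id, label = label,
                    scores[cols])
  rownames(out) <- NULL
  sep <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
  attr(out, "centroids") <- centroids
  attr(out, "separation") <- sep
  attr(out, "plot_radius") <- 0.9 * sep
  class(out) <- c("cohort_assignment", "data.frame")
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent
#' ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  expd <- si * sj / ch2(length(a))
  mx <- (si + sj) / 2
  if (mx == expd) return(1)
  (sij - expd) / (mx - expd)
}
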