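# Paired topographic tests with nonparametric permutation cluster
# correction, and paired condition contrasts.

topo_values <- function(x) {
  if (inherits(x, "band_topography")) x$values else x
}

#' Per-channel paired t-test between two topographies
#'
#' @param topos_a,topos_b Lists (one element per subject) of
#'   `band_topography` objects or named numeric vectors, on a common channel
#'   set; or subjects x channels matrices.
#' @return List of class `topo_stat`: `t_map`, `p_map` (uncorrected,
#'   two-sided, df = n_subjects - 1), `df`, `diffs` (subjects x channels),
#'   `labels`; `sig_mask`/`min_cluster` are filled by
#'   [permutation_cluster_correct()]. Channels with zero difference variance
#'   get `t = +-Inf` (or 0 when the mean difference is also 0).
#' @export
paired_topo_test <- function(topos_a, topos_b) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, topo_values))
  }
  A <- as_mat(topos_a)
  B <- as_mat(topos_b)
  if (!identical(dim(A), dim(B)) || !identical(colnames(A), colnames(B)))
    stopf("channel sets or subject counts differ between conditions")
  n <- nrow(A)
  if (n < 2) stopf("need >= 2 subjects")
  D <- B - A
  m <- colMeans(D)
  s <- apply(D, 2, sd)
  t_map <- ifelse(s > 0, m / (s / sqrt(n)),
                  ifelse(m == 0, 0, sign(m) * Inf))
  p_map <- 2 * pt(-abs(t_map), df = n - 1)
  structure(list(t_map = t_map, p_map = p_map, df = n - 1, diffs = D,
                 labels = colnames(A), sig_mask = NULL, min_cluster = NA),
            class = "topo_stat")
}

# Connected components among `active` labels in the montage neighbor graph,
# returned as a list of label vectors.
graph_clusters <- function(active, neighbor_map) {
  comps <- list()
  left <- active
  while (length(left) > 0) {
    queue <- left[1]
    comp <- character()
    while (length(queue) > 0) {
      ch <- queue[1]
      queue <- queue[-1]
      if (ch %in% comp) next
      comp <- c(comp, ch)
      queue <- c(queue, intersect(neighbor_map[[ch]], setdiff(left, comp)))
    }
    comps[[length(comps) + 1]] <- comp
    left <- setdiff(left, comp)
  }
  comps
}

# Largest same-sign supra-threshold cluster size for a t-map.
max_cluster_size <- function(t_map, labels, neighbor_map, tcrit) {
  best <- 0L
  for (sgn in c(1, -1)) {
    active <- labels[sgn * t_map > tcrit]
    if (length(active) == 0) next
    sizes <- vapply(graph_clusters(active, neighbor_map), length, 1L)
    best <- max(best, sizes)
  }
  best
}

#' Permutation cluster correction of a paired topographic test
#'
#' Sign-flip permutation over subjects: for each sign assignment (all `2^n`
#' when `n_perm == 2^n`; the identity assignment is always included) the
#' paired t-map is recomputed, thresholded at uncorrected two-sided
#' p < 0.05, and the maximal same-sign cluster size in the montage
#' neighbor graph is recorded. The minimum significant cluster size is the
#' 95th percentile of that null distribution, floored at 3 neighboring
#' electrodes; observed clusters at least that large form `sig_mask`. With
#' 5 subjects and all 32 flips the achievable family-wise rate is 1/16
#' (the observed assignment and its global mirror both sit in the null),
#' just above the nominal 5%.
#'
#' @param result A `topo_stat` from [paired_topo_test()].
#' @param montage An `eeg_montage` with a neighbor graph covering the
#'   result's labels.
#' @param n_perm Number of sign flips; at most `2^n_subjects` (error
#'   beyond). When below `2^n`, that many assignments are drawn without
#'   replacement from the full set (identity included).
#' @return The `topo_stat` with `sig_mask`, `min_cluster`, `null_max` and
#'   `clusters` (observed supra-threshold clusters with sizes) filled in.
#' @export
permutation_cluster_correct <- function(result, montage, n_perm = NULL) {
  stopifnot(inherits(result, "topo_stat"), inherits(montage, "eeg_montage"))
  if (is.null(montage$neighbor_map)) stopf("montage has no neighbor graph")
  D <- result$diffs
  n <- nrow(D)
  n_perm <- n_perm %||% 2^n
  if (n_perm > 2^n)
    stopf("n_perm (%d) exceeds 2^n_subjects (%d)", n_perm, 2^n)
  labels <- result$labels
  nb <- montage$neighbor_map
  tcrit <- qt(0.975, df = n - 1)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))[, n:1, drop = FALSE]
  if (n_perm < 2^n) {
    pick <- c(1L, sample(2:2^n, n_perm - 1L))
    signs <- signs[pick, , drop = FALSE]
  }
  # vectorised t-maps for all flips: flip only changes the mean's sign
  # pattern, the per-channel sum of squares is invariant
  M <- (signs %*% D) / n                       # flips x channels means
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)   # flips x channels variances
  V[V < 0] <- 0
  Tm <- M / sqrt(V / n)
  Tm[V == 0] <- ifelse(M[V == 0] == 0, 0, sign(M[V == 0]) * Inf)
  null_max <- vapply(seq_len(nrow(Tm)), function(k)
    max_cluster_size(Tm[k, ], labels, nb, tcrit), 0L)
  # 95th percentile as an order statistic of the sign-flip null (which
  # contains the observed assignment and its global mirror), floored at 3
  min_cluster <- max(3L, sort(null_max)[ceiling(0.95 * length(null_max))])
  observed <- list()
  for (sgn in c(1, -1)) {
    active <- labels[sgn * result$t_map > tcrit]
    if (length(active) > 0)
      observed <- c(observed, graph_clusters(active, nb))
  }
  sizes <- vapply(observed, length, 1L)
  sig <- unlist(observed[sizes >= min_cluster])
  result$min_cluster <- min_cluster
  result$null_max <- null_max
  result$clusters <- observed
  result$sig_mask <- if (is.null(sig)) character() else sig
  result
}

#' Paired condition contrasts
#'
#' For every ordered pair of conditions (later vs earlier in column order),
#' the per-subject difference is summarised as mean +- sem with a two-sided
#' paired t-test.
#'
#' @param values Subjects x conditions numeric matrix (column names are the
#'   condition labels), or a data frame with `subject`, `condition`,
#'   `value` columns. Missing cells are an error listing subject and
#'   condition.
#' @return Data frame with one row per contrast: `contrast`, `mean_diff`,
#'   `sem`, `t`, `df` (= n_subjects - 1), `p`.
#' @export
condition_contrast <- function(values) {
  if (is.data.frame(values)) {
    check_columns(values, c("subject", "condition", "value"), "contrast input")
    conds <- unique(values$condition)
    subs <- unique(values$subject)
    M <- matrix(NA_real_, length(subs), length(conds),
                dimnames = list(subs, conds))
    M[cbind(match(values$subject, subs), match(values$condition, conds))] <-
      values$value
    values <- M
  }
  if (any(is.na(values))) {
    idx <- which(is.na(values), arr.ind = TRUE)
    stopf("missing cell(s): %s",
          paste(sprintf("%s/%s", rownames(values)[idx[, 1]],
                        colnames(values)[idx[, 2]]), collapse = ", "))
  }
  n <- nrow(values)
  if (n < 2 || ncol(values) < 2)
    stopf("need >= 2 subjects and >= 2 conditions")
  conds <- colnames(values) %||% paste0("cond", seq_len(ncol(values)))
  rows <- list()
  for (i in seq_len(ncol(values) - 1)) {
    for (j in (i + 1):ncol(values)) {
      d <- values[, j] - values[, i]
      sem <- sd(d) / sqrt(n)
      t <- if (sem > 0) mean(d) / sem else
        ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf)
      rows[[length(rows) + 1]] <- data.frame(
        contrast = sprintf("%s-%s", conds[j], conds[i]),
        mean_diff = mean(d), sem = sem, t = t, df = n - 1,
        p = 2 * pt(-abs(t), df = n - 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
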