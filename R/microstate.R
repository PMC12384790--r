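#' Global field power
#'
#' Spatial standard deviation of the potential across channels at each
#' sample: `GFP_t = sqrt( sum_i (u_it - mean_t)^2 / N )` with `N` the
#' channel count. Peaks of this curve mark moments of maximal topographic
#' signal-to-noise and are the raw material for microstate clustering.
#'
#' @param x An [eeg_recording()], [eeg_epoch()] or channels x samples
#'   matrix with >= 2 channels.
#' @return Numeric vector, one non-negative value per sample.
#' @examples
#' gfp(matrix(c(2, 0, -2, 0), 4, 1))  # sqrt(8/4)
#' @export
gfp <- function(x) {
  m <- as_data_matrix(x)
  if (nrow(m) < 2L) stopf("GFP needs >= 2 channels")
  centered <- sweep(m, 2, colMeans(m))
  sqrt(colSums(centered^2) / nrow(m))
}

#' Strict local maxima of a GFP series
#'
#' @param gfp_series Numeric vector of length >= 3.
#' @return Integer vector of 1-based indices of samples strictly greater
#'   than both neighbours; endpoints are never peaks. May be empty.
#' @export
gfp_peaks <- function(gfp_series) {
  n <- length(gfp_series)
  if (n < 3L) stopf("need a series of length >= 3")
  core <- gfp_series[2:(n - 1)]
  which(core > gfp_series[1:(n - 2)] & core > gfp_series[3:n]) + 1L
}

# Center columns (maps) and scale to unit norm; drops zero-variance maps.
# Returns list(V = channels x M unit maps, gfp = spatial sd per map, keep).
prepare_maps <- function(maps) {
  nch <- nrow(maps)
  V <- sweep(maps, 2, colMeans(maps))
  g <- sqrt(colSums(V^2) / nch)
  keep <- g > 1e-14
  V <- V[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  list(V = V, gfp = g[keep], keep = keep)
}

# Polarity-invariant cluster prototype: first principal component of the
# member maps (unit-norm columns of V).
cluster_prototype <- function(V_members) {
  if (ncol(V_members) == 1L) {
    p <- V_members[, 1]
    return(p / sqrt(sum(p^2)))
  }
  S <- tcrossprod(V_members)         # channels x channels
  ev <- eigen(S, symmetric = TRUE)
  p <- ev$vectors[, 1]
  p / sqrt(sum(p^2))
}

#' Atomize-and-agglomerate hierarchical clustering of topographic maps
#'
#' Polarity-invariant AAHC: every map starts as a singleton cluster; at
#' each step the cluster contributing least global explained variance is
#' dissolved and its members are reassigned to the remaining cluster of
#' maximal absolute spatial correlation. Cluster prototypes are the first
#' principal component of the member maps, so a map and its negation are
#' treated identically. Template sets are snapshotted at every cluster
#' count in `k_range`.
#'
#' @param peak_maps Channels x M matrix of topographies (typically the maps
#'   at GFP peaks), M >= `max(k_range)`.
#' @param k_range Integer vector of template counts to return
#'   (default `1:10`).
#' @param max_maps Upper bound on the number of maps entering the
#'   clustering; larger inputs are thinned by even subsampling
#'   (default 1000). Keeps the quadratic agglomeration affordable on long
#'   recordings without biasing the time course.
#' @param refine Polish the partition reported at each K by fixed-point
#'   iteration (reassign every map to the prototype of maximal absolute
#'   correlation, recompute prototypes, repeat until stable; default
#'   TRUE). The polish corrects occasional greedy mis-merges of the
#'   agglomerative path and leaves the path itself untouched, so results
#'   remain deterministic.
#' @return Named list (one element per K, names `"K<k>"`) of
#'   [template_set()] objects carrying per-template and total GEV and the
#'   SSE of the training maps.
#' @export
aahc_cluster <- function(peak_maps, k_range = 1:10, max_maps = 1000,
                         refine = TRUE) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stopf("k_range must be >= 1")
  pm <- as_data_matrix(peak_maps)
  if (ncol(pm) > max_maps) {
    keep <- unique(round(seq(1, ncol(pm), length.out = max_maps)))
    pm <- pm[, keep, drop = FALSE]
  }
  prep <- prepare_maps(pm)
  V <- prep$V
  gfp2 <- prep$gfp^2
  M <- ncol(V)
  if (M < max(k_range))
    stopf("only %d usable maps for K up to %d", M, max(k_range))
  denom <- sum(gfp2)

  assign <- seq_len(M)                 # cluster id per map
  protos <- V                          # prototype per cluster (by id)
  alive <- rep(TRUE, M)
  # per-map GEV contribution wrt its cluster prototype
  contrib <- gfp2                      # singleton: corr = 1
  cluster_gev <- gfp2
  members <- as.list(seq_len(M))

  snapshots <- vector("list", length(k_range))
  names(snapshots) <- sprintf("K%d", k_range)
  take_snapshot <- function(ncl) {
    pos <- match(ncl, k_range)
    if (is.na(pos)) return()
    ids <- which(alive)
    P <- protos[, ids, drop = FALSE]
    labels <- match(assign, ids)
    if (isTRUE(refine))
      for (it in 1:50) {
        new_lab <- apply(abs(crossprod(P, V)), 2, which.max)
        if (all(new_lab == labels)) break
        labels <- new_lab
        for (k in seq_len(ncol(P))) {
          mem <- which(labels == k)
          if (!length(mem)) next     # emptied cluster keeps its prototype
          P[, k] <- cluster_prototype(
            V[, mem, drop = FALSE] *
              rep(prep$gfp[mem], each = nrow(V)))
        }
      }
    rc <- abs(crossprod(P, V))[cbind(labels, seq_len(M))]
    gev_t <- vapply(seq_len(ncol(P)), function(k)
      sum(gfp2[labels == k] * rc[labels == k]^2), 0) / denom
    ts <- template_set(t(P), gev_total = sum(gev_t),
                       gev_per_template = gev_t)
    ts$sse <- sse(ts, pm)
    attr(ts, "training_assignment") <- labels
    snapshots[[pos]] <<- ts
  }

  ncl <- M
  take_snapshot(ncl)
  while (ncl > min(k_range)) {
    ids <- which(alive)
    worst <- ids[which.min(cluster_gev[ids])]
    mem <- members[[worst]]
    alive[worst] <- FALSE
    ids <- which(alive)
    # reassign dissolved members by max |corr| with remaining prototypes
    r <- crossprod(protos[, ids, drop = FALSE], V[, mem, drop = FALSE])
    target <- ids[apply(abs(r), 2, which.max)]
    touched <- unique(target)
    for (k in seq_along(mem)) {
      members[[target[k]]] <- c(members[[target[k]]], mem[k])
      assign[mem[k]] <- target[k]
    }
    members[[worst]] <- integer()
    cluster_gev[worst] <- 0
    # refresh prototypes and contributions of clusters that gained members
    for (cl in touched) {
      protos[, cl] <- cluster_prototype(V[, members[[cl]], drop = FALSE])
      rr <- as.vector(crossprod(V[, members[[cl]], drop = FALSE],
                                protos[, cl]))
      contrib[members[[cl]]] <- gfp2[members[[cl]]] * rr^2
      cluster_gev[cl] <- sum(contrib[members[[cl]]])
    }
    ncl <- ncl - 1L
    take_snapshot(ncl)
  }
  if (any(vapply(snapshots, is.null, TRUE)))
    stopf("internal error: missing snapshot for some K")
  snapshots
}

#' Global explained variance of a template assignment
#'
#' `GEV = sum_n GFP_n^2 Corr(x_n, a_{l(n)})^2 / sum_n GFP_n^2`, where
#' `l(n)` assigns map `n` to a template (by maximal absolute spatial
#' correlation when not supplied).
#'
#' @param templates A [template_set()] (or K x channels matrix).
#' @param maps Channels x M matrix of topographies.
#' @param gfp_values Optional per-map GFP; computed from `maps` when
#'   missing.
#' @param assignment Optional integer template index per map.
#' @return Scalar in `[0, 1]`, with per-template contributions in the
#'   `"per_template"` attribute.
#' @export
gev <- function(templates, maps, gfp_values = NULL, assignment = NULL) {
  tm <- if (inherits(templates, "template_set")) templates$maps else
    normalize_maps(templates)
  m <- as_data_matrix(maps)
  prep <- prepare_maps(m)
  g2 <- (gfp_values %||% prep$gfp)^2
  if (sum(g2) <= 0) stopf("total GFP is zero; GEV undefined")
  r <- crossprod(prep$V, t(tm))          # M x K correlations
  if (is.null(assignment)) {
    assignment <- apply(abs(r), 1, which.max)
  } else {
    assignment <- assignment[prep$keep]
  }
  rc <- r[cbind(seq_len(nrow(r)), assignment)]
  per <- vapply(seq_len(nrow(tm)), function(k)
    sum(g2[assignment == k] * rc[assignment == k]^2), 0) / sum(g2)
  structure(sum(per), per_template = per)
}

#' Sum of squared errors of templates against data
#'
#' For every sample map the assigned template (maximal absolute spatial
#' correlation) is scaled to the least-squares amplitude and the squared
#' Euclidean residual is accumulated:
#' `SSE = sum_n || M_n - a_n Ms_{l(n)} ||^2` with
#' `a_n = <M_n, Ms_{l(n)}>`. Maps are spatially centered first; scaling
#' keeps the measure polarity-invariant.
#'
#' @param templates A [template_set()] or K x channels matrix.
#' @param data Channels x N matrix (or recording/epoch) of sample maps.
#' @return Non-negative scalar.
#' @export
sse <- function(templates, data) {
  tm <- if (inherits(templates, "template_set")) templates$maps else
    normalize_maps(templates)
  x <- as_data_matrix(data)
  xc <- sweep(x, 2, colMeans(x))
  a <- crossprod(xc, t(tm))              # N x K inner products (LS amp)
  best <- apply(abs(a), 1, max)          # residual minimized by max |a|
  sum(colSums(xc^2) - best^2)
}

#' Select the template count by the elbow criterion
#'
#' Among candidate K whose GEV reaches `gev_threshold`, returns the K
#' maximizing the discrete second difference of the SSE curve on the
#' logarithmic scale (`log SSE(K-1) - 2 log SSE(K) + log SSE(K+1)`); ties
#' break to the smallest K. The log scale makes the curvature statistic
#' scale-free — it detects the change in successive improvement ratios —
#' which keeps the elbow stable under the GFP weighting of the absolute
#' SSE curve. A curvature-free (linear or geometric) SSE decay falls back
#' to the smallest admissible K with a warning.
#'
#' @param sse_by_k Numeric SSE values on a contiguous K grid.
#' @param gev_by_k GEV values on the same grid.
#' @param k_values The K grid (default `seq_along(sse_by_k)`).
#' @param gev_threshold Minimum admissible GEV (default 0.65).
#' @return Selected K (integer).
#' @export
select_k_elbow <- function(sse_by_k, gev_by_k,
                           k_values = seq_along(sse_by_k),
                           gev_threshold = 0.65) {
  stopifnot(length(sse_by_k) == length(gev_by_k),
            length(k_values) == length(sse_by_k))
  if (any(diff(k_values) != 1))
    stopf("k_values must be contiguous for second differences")
  pass <- gev_by_k >= gev_threshold
  if (!any(pass))
    stopf("no K reaches GEV >= %.2f (attained: %s)", gev_threshold,
          paste(sprintf("K=%d:%.3f", k_values, gev_by_k), collapse = ", "))
  n <- length(k_values)
  if (n < 3L) {
    warnf("fewer than 3 K values: no curvature; returning smallest K passing the GEV threshold")
    return(k_values[which(pass)[1]])
  }
  # floor protects exactly-zero SSE (noiseless data); the log kink then
  # lands on the first K reaching zero
  ls <- log(pmax(sse_by_k, max(sse_by_k) * 1e-12, .Machine$double.xmin))
  d2 <- rep(NA_real_, n)
  d2[2:(n - 1)] <- ls[1:(n - 2)] - 2 * ls[2:(n - 1)] + ls[3:n]
  cand <- which(pass & !is.na(d2))
  if (!length(cand)) {
    warnf("GEV threshold only met at boundary K; returning smallest passing K")
    return(k_values[which(pass)[1]])
  }
  if (max(d2[cand]) <= 1e-9) {
    warnf("SSE decay has no elbow (curvature ~ 0); returning smallest K passing the GEV threshold")
    return(k_values[which(pass)[1]])
  }
  best <- cand[d2[cand] == max(d2[cand])]
  k_values[min(best)]
}

#' Back-fit templates to an epoch
#'
#' Labels every sample with the template of maximal absolute spatial
#' correlation, converting the EEG into a microstate sequence. Ties break
#' to the lowest template index; zero-variance samples inherit the previous
#' label (the first such sample gets label 1).
#'
#' @param templates A [template_set()].
#' @param epoch An [eeg_epoch()], [eeg_recording()] or channels x samples
#'   matrix.
#' @param fs Sampling rate when `epoch` is a bare matrix.
#' @param min_duration_ms Optional minimal segment duration; runs shorter
#'   than this are absorbed into the neighbouring template of higher mean
#'   absolute correlation (default 0 = no smoothing).
#' @return A [label_sequence()].
#' @export
backfit <- function(templates, epoch, fs = NULL, min_duration_ms = 0) {
  stopifnot(inherits(templates, "template_set"))
  x <- as_data_matrix(epoch)
  fs <- fs %||% get_fs(epoch)
  if (is.null(fs)) stopf("`fs` required when back-fitting a bare matrix")
  if (nrow(x) != ncol(templates$maps))
    stopf("channel count mismatch: data %d vs templates %d",
          nrow(x), ncol(templates$maps))
  xc <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(colSums(xc^2))
  ok <- nrm > 1e-14
  r <- matrix(0, ncol(x), templates$K)
  if (any(ok))
    r[ok, ] <- t(abs(templates$maps %*%
                       sweep(xc[, ok, drop = FALSE], 2, nrm[ok], "/")))
  labels <- max.col(r, ties.method = "first")
  if (any(!ok)) {
    message(sprintf("%d zero-variance sample(s): carried previous label",
                    sum(!ok)))
    for (i in which(!ok)) labels[i] <- if (i == 1L) 1L else labels[i - 1L]
  }
  if (min_duration_ms > 0)
    labels <- enforce_min_duration(labels, r,
                                   round(min_duration_ms / 1000 * fs))
  label_sequence(labels, fs = fs, K = templates$K)
}

# Absorb runs shorter than min_len samples into the neighbouring label
# with the higher mean |correlation| over the run.
enforce_min_duration <- function(labels, corr_abs, min_len) {
  if (min_len <= 1L) return(labels)
  for (pass in 1:10) {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    short <- short[!(short %in% c(1L, length(r$lengths))) |
                     length(r$lengths) > 1L]
    if (!length(short)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (s in short) {
      idx <- starts[s]:ends[s]
      left <- if (s > 1L) r$values[s - 1L] else NA_integer_
      right <- if (s < length(r$values)) r$values[s + 1L] else NA_integer_
      cand <- stats::na.omit(c(left, right))
      if (!length(cand)) next
      sc <- vapply(cand, function(l) mean(corr_abs[idx, l]), 0)
      labels[idx] <- cand[which.max(sc)]
      changed <- TRUE
    }
    if (!changed) break
  }
  labels
}

#' Conventional microstate parameters of a label sequence
#'
#' @param seq A [label_sequence()].
#' @return A list of class `microstate_params`:
#'   \describe{
#'     \item{coverage}{fraction of samples per template (sums to 1).}
#'     \item{mean_duration_ms}{mean contiguous-run length per template, ms
#'       (NA for templates that never occur).}
#'     \item{occurrence_per_s}{runs per second per template.}
#'     \item{transition_matrix}{run-level (segment-to-segment) transition
#'       probabilities; rows sum to 1 for states with outgoing
#'       transitions.}
#'   }
#' @examples
#' p <- microstate_params(label_sequence(c(1, 1, 2, 2, 2), fs = 5))
#' p$coverage            # 0.4 0.6
#' p$mean_duration_ms    # 400 600
#' @export
microstate_params <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  lab <- seq$labels
  K <- seq$K
  n <- length(lab)
  dur_s <- n / seq$fs
  cov <- tabulate(lab, K) / n
  r <- rle(lab)
  mean_dur <- rep(NA_real_, K)
  occ <- numeric(K)
  for (k in seq_len(K)) {
    runs <- r$lengths[r$values == k]
    occ[k] <- length(runs) / dur_s
    if (length(runs)) mean_dur[k] <- mean(runs) / seq$fs * 1000
  }
  TM <- matrix(0, K, K)
  if (length(r$values) > 1L) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1]
    for (i in seq_along(from)) TM[from[i], to[i]] <- TM[from[i], to[i]] + 1
    rs <- rowSums(TM)
    TM[rs > 0, ] <- TM[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  nm <- sprintf("Ms%d", seq_len(K))
  structure(list(coverage = setNames(cov, nm),
                 mean_duration_ms = setNames(mean_dur, nm),
                 occurrence_per_s = setNames(occ, nm),
                 transition_matrix = matrix(TM, K, K,
                                            dimnames = list(nm, nm))),
            class = "microstate_params")
}

#' @export
print.microstate_params <- function(x, ...) {
  cat("<microstate_params>\n")
  print(round(rbind(coverage = x$coverage,
                    mean_duration_ms = x$mean_duration_ms,
                    occurrence_per_s = x$occurrence_per_s), 4))
  invisible(x)
}

#' Fit microstates to one or more epochs
#'
#' Convenience pipeline: concatenates GFP-peak maps across the supplied
#' epochs (group-level clustering), runs AAHC over `k_range`, selects K by
#' the elbow criterion under the GEV threshold, and back-fits the selected
#' templates to every epoch.
#'
#' @param epochs A single epoch/recording or a list of them (all with the
#'   same channel count and sampling rate).
#' @param k_range Candidate template counts (default `1:10`).
#' @param gev_threshold Minimum admissible GEV (default 0.65).
#' @param max_maps Subsampling cap passed to [aahc_cluster()].
#' @param min_duration_ms Back-fit smoothing passed to [backfit()].
#' @return List with elements `K` (selected), `templates`
#'   ([template_set()] at the selected K), `by_k` (all template sets),
#'   `sse_by_k`, `gev_by_k`, `sequences` (list of [label_sequence()]),
#'   `n_peak_maps`.
#' @export
fit_microstates <- function(epochs, k_range = 1:10, gev_threshold = 0.65,
                            max_maps = 1000, min_duration_ms = 0) {
  if (inherits(epochs, c("eeg_epoch", "eeg_recording")))
    epochs <- list(epochs)
  peak_list <- lapply(epochs, function(e) {
    x <- as_data_matrix(e)
    pk <- gfp_peaks(gfp(x))
    x[, pk, drop = FALSE]
  })
  peaks <- do.call(cbind, peak_list)
  by_k <- aahc_cluster(peaks, k_range = k_range, max_maps = max_maps)
  k_values <- as.integer(sub("^K", "", names(by_k)))
  sse_by_k <- vapply(by_k, function(ts) ts$sse, 0)
  gev_by_k <- vapply(by_k, function(ts) ts$gev_total, 0)
  K <- select_k_elbow(sse_by_k, gev_by_k, k_values,
                      gev_threshold = gev_threshold)
  templates <- by_k[[sprintf("K%d", K)]]
  seqs <- lapply(epochs, function(e)
    backfit(templates, e, min_duration_ms = min_duration_ms))
  list(K = K, templates = templates, by_k = by_k,
       sse_by_k = setNames(sse_by_k, names(by_k)),
       gev_by_k = setNames(gev_by_k, names(by_k)),
       sequences = seqs, n_peak_maps = ncol(peaks))
}
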