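#' Event log of bleeding detections
#'
#' @param times Non-negative event times in seconds (sorted internally).
#' @param source `"human"` or `"machine"`.
#' @param video_id Identifier of the video the events belong to.
#' @return An `event_log` list.
#' @export
event_log <- function(times, source = c("human", "machine"), video_id = "v1") {
  source <- match.arg(source)
  if (any(times < 0)) stop_validation("event times must be non-negative")
  structure(list(times = sort(as.numeric(times)), source = source,
                 video_id = video_id),
            class = "event_log")
}

#' Match machine events to human annotations
#'
#' Greedy nearest-in-time one-to-one matching within a symmetric
#' tolerance: candidate pairs are taken in order of increasing absolute
#' time difference; each matched pair is a true positive with
#' `delta_s = machine_time - human_time` (negative = machine earlier).
#' Unmatched machine events are false positives; unmatched human events
#' are false negatives.
#'
#' @param machine,human `event_log` objects from the same video.
#' @param tolerance_s Maximum |delta| for a match (default 10 s; bleeding
#'   episodes are sparse relative to this window in prostatectomy video).
#' @return A `match_result` list: `pairs` (data frame `machine_time`,
#'   `human_time`, `delta_s`), counts `tp`, `fp`, `fn`, and
#'   `outcome_per_event` (data frame `time_s`, `source`, `outcome`).
#' @examples
#' m <- event_log(c(10, 30), "machine")
#' h <- event_log(c(12.5, 50), "human")
#' match_events(m, h, tolerance_s = 5)
#' @export
match_events <- function(machine, human, tolerance_s = 10) {
  stopifnot(inherits(machine, "event_log"), inherits(human, "event_log"))
  if (!identical(machine$video_id, human$video_id)) {
    stop_validation("event logs come from different videos (%s vs %s)",
                    machine$video_id, human$video_id)
  }
  mt <- machine$times
  ht <- human$times
  cand <- expand.grid(i = seq_along(mt), j = seq_along(ht))
  if (nrow(cand) > 0) {
    cand$adelta <- abs(mt[cand$i] - ht[cand$j])
    cand <- cand[cand$adelta <= tolerance_s, , drop = FALSE]
    cand <- cand[order(cand$adelta, cand$i, cand$j), , drop = FALSE]
  }
  used_m <- logical(length(mt))
  used_h <- logical(length(ht))
  pi <- pj <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_m[i] && !used_h[j]) {
      used_m[i] <- used_h[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j)
    }
  }
  ord <- order(mt[pi])
  pairs <- data.frame(machine_time = mt[pi][ord], human_time = ht[pj][ord],
                      delta_s = (mt[pi] - ht[pj])[ord])
  outcome <- data.frame(
    time_s = c(mt[used_m], mt[!used_m], ht[!used_h]),
    source = c(rep("machine", sum(used_m) + sum(!used_m)),
               rep("human", sum(!used_h))),
    outcome = c(rep("TP", sum(used_m)), rep("FP", sum(!used_m)),
                rep("FN", sum(!used_h))),
    stringsAsFactors = FALSE
  )
  outcome <- outcome[order(outcome$time_s), , drop = FALSE]
  rownames(outcome) <- NULL
  structure(list(pairs = pairs, tp = sum(used_m), fp = sum(!used_m),
                 fn = sum(!used_h), outcome_per_event = outcome,
                 video_id = machine$video_id),
            class = "match_result")
}

#' Delta-time statistics of matched events
#'
#' Median and interquartile range (type-7 quantiles) of
#' `delta_s = machine_time - human_time`. A negative median means the
#' machine detects earlier than the human; `lead_median_s = -median_s` is
#' reported alongside to avoid sign ambiguity.
#'
#' @param result A `match_result` (or a numeric vector of deltas).
#' @return List with `median_s`, `iqr_s`, `lead_median_s`, `n`.
#' @examples
#' delta_stats(c(-1, -2, -3, -4, -5))  # median -3, IQR 2
#' @export
delta_stats <- function(result) {
  deltas <- if (inherits(result, "match_result")) result$pairs$delta_s
            else as.numeric(result)
  if (length(deltas) == 0) {
    stop_validation("delta statistics undefined without matched pairs")
  }
  q <- quantile(deltas, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median_s = q[2], iqr_s = q[3] - q[1], lead_median_s = -q[2],
       n = length(deltas))
}

#' Gaussian kernel density estimate of delta times
#'
#' Smoothed probability-density representation of the observed machine
#' minus human detection-time differences. Bandwidth defaults to
#' Silverman's rule of thumb; degenerate zero-variance data fall back to
#' a fixed minimal bandwidth and are flagged.
#'
#' @param deltas Numeric vector of delta times (seconds).
#' @param bandwidth `"silverman"` or a positive number.
#' @param n Grid size of the returned curve.
#' @return A `kde_density` list: `x`, `y`, `bandwidth`, `fallback`.
#' @export
kde_density <- function(deltas, bandwidth = "silverman", n = 512) {
  deltas <- as.numeric(deltas)
  fallback <- FALSE
  if (is.character(bandwidth)) {
    if (length(deltas) < 2) {
      stop_validation("automatic bandwidth needs at least 2 observations")
    }
    if (var(deltas) == 0) {
      bw <- 0.1
      fallback <- TRUE
      warning("zero-variance deltas: falling back to fixed bandwidth 0.1")
    } else {
      bw <- stats::bw.nrd0(deltas)
    }
  } else {
    bw <- as.numeric(bandwidth)
    if (bw <= 0) stop_validation("bandwidth must be positive")
  }
  # exact direct evaluation of the Gaussian mixture (event logs are small,
  # so no binned approximation is needed)
  x <- seq(min(deltas) - 4 * bw, max(deltas) + 4 * bw, length.out = n)
  y <- rowMeans(stats::dnorm(outer(x, deltas, "-"), sd = bw))
  structure(list(x = x, y = y, bandwidth = bw, fallback = fallback,
                 n_obs = length(deltas)),
            class = "kde_density")
}

#' @export
plot.kde_density <- function(x, ...) {
  plot(x$x, x$y, type = "l", xlab = "delta time (s): machine - human",
       ylab = "density", main = "Detection delta-time density")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Multiple correspondence analysis of a categorical table
#'
#' Indicator-matrix MCA: the N x J 0/1 indicator matrix Z of Q
#' categorical variables is analysed by correspondence analysis
#' (correspondence matrix P = Z / sum(Z), standardised residuals,
#' singular value decomposition). Principal inertias are the squared
#' singular values and always sum to (J - Q) / Q. Variables are
#' summarised per dimension by their squared correlations
#' (discrimination measures, the correlation ratio eta^2 between the
#' individual scores and the variable), which lie in `[0, 1]` and are
#' the natural variable coordinates. Individuals get principal
#' coordinates.
#'
#' @param table Data frame of categorical variables (factors or
#'   characters), one row per individual. Variables with a single
#'   observed category are dropped with a warning.
#' @param n_dims Number of dimensions to retain.
#' @param correction `"none"` (raw indicator inertias) or `"benzecri"`
#'   (Benzecri-adjusted inertias, reported alongside).
#' @return An `mca_result` list: `principal_inertias`,
#'   `variable_sq_correlations` (Q x n_dims), `individual_coordinates`
#'   (N x n_dims), `category_coordinates`, `total_inertia`, `J`, `Q`.
#' @export
mca <- function(table, n_dims = 2, correction = c("none", "benzecri")) {
  correction <- match.arg(correction)
  table <- as.data.frame(table, stringsAsFactors = TRUE)
  if (ncol(table) < 2) stop_validation("MCA needs at least 2 variables")
  if (anyNA(table)) stop_validation("MCA input must have no missing values")
  table[] <- lapply(table, function(col) factor(as.character(col)))
  constant <- vapply(table, function(col) nlevels(col) < 2, logical(1))
  if (any(constant)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(names(table)[constant], collapse = ", ")))
    table <- table[, !constant, drop = FALSE]
  }
  if (ncol(table) < 2) {
    stop_validation("fewer than 2 non-constant variables remain")
  }
  n <- nrow(table)
  Q <- ncol(table)
  Zs <- lapply(names(table), function(nm) {
    f <- table[[nm]]
    z <- matrix(0, n, nlevels(f),
                dimnames = list(NULL, paste(nm, levels(f), sep = ":")))
    z[cbind(seq_len(n), as.integer(f))] <- 1
    z
  })
  Z <- do.call(cbind, Zs)
  J <- ncol(Z)
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cm) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  inertias <- sv$d[keep]^2
  n_dims <- min(n_dims, length(keep))
  # individual principal coordinates
  Frow <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = length(keep))
  Gcol <- diag(1 / sqrt(cm)) %*% sv$v[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = length(keep))
  rownames(Gcol) <- colnames(Z)
  # squared correlations (discrimination measures): eta^2 of scores ~ variable
  sq <- matrix(NA_real_, Q, n_dims,
               dimnames = list(names(table), paste0("dim", seq_len(n_dims))))
  for (k in seq_len(n_dims)) {
    f <- Frow[, k]
    tot <- sum((f - mean(f))^2)
    for (q in seq_len(Q)) {
      g <- table[[q]]
      means <- tapply(f, g, mean)
      between <- sum(tabulate(as.integer(g)) * (means - mean(f))^2)
      sq[q, k] <- if (tot > 0) between / tot else 0
    }
  }
  adjusted <- NULL
  if (correction == "benzecri") {
    thr <- 1 / Q
    lam <- inertias[inertias > thr]
    adjusted <- ((Q / (Q - 1)) * (lam - thr))^2
  }
  structure(list(
    principal_inertias = inertias,
    variable_sq_correlations = sq,
    individual_coordinates = Frow[, seq_len(n_dims), drop = FALSE],
    category_coordinates = Gcol[, seq_len(n_dims), drop = FALSE],
    adjusted_inertias = adjusted,
    total_inertia = sum(inertias),
    J = J, Q = Q, n = n
  ), class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA: %d individuals, %d variables, %d categories\n",
              x$n, x$Q, x$J))
  cat(sprintf("  total inertia %.4f (expected (J-Q)/Q = %.4f)\n",
              x$total_inertia, (x$J - x$Q) / x$Q))
  k <- min(5, length(x$principal_inertias))
  cat("  leading principal inertias:",
      paste(sprintf("%.4f", x$principal_inertias[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.mca_result <- function(x, dims = c(1, 2), what = c("variables",
                                                        "individuals"), ...) {
  what <- match.arg(what)
  if (what == "variables") {
    sq <- x$variable_sq_correlations[, dims, drop = FALSE]
    plot(sq[, 1], sq[, 2], xlim = c(0, 1), ylim = c(0, 1),
         xlab = sprintf("dim %d squared correlation", dims[1]),
         ylab = sprintf("dim %d squared correlation", dims[2]),
         main = "Variable discrimination")
    graphics::text(sq[, 1], sq[, 2], rownames(sq), pos = 3, cex = 0.8)
  } else {
    co <- x$individual_coordinates[, dims, drop = FALSE]
    plot(co[, 1], co[, 2],
         xlab = sprintf("dim %d", dims[1]), ylab = sprintf("dim %d", dims[2]),
         main = "Individuals")
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(x)
}

#' Read or write event-log CSV files
#'
#' The CSV schema is `video_id, source, time_s, flag`.
#'
#' @param path CSV path.
#' @return `read_event_logs()` returns a list of `event_log` objects,
#'   one per (video_id, source) combination.
#' @export
read_event_logs <- function(path) {
  if (!file.exists(path)) stop_io("event log not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "source", "time_s")
  if (!all(need %in% names(df))) {
    stop_validation("event CSV must have columns: %s",
                    paste(need, collapse = ", "))
  }
  out <- list()
  for (vid in unique(df$video_id)) {
    for (src in unique(df$source[df$video_id == vid])) {
      sel <- df$video_id == vid & df$source == src
      key <- paste(vid, src, sep = "/")
      out[[key]] <- event_log(df$time_s[sel],
                              source = if (src == "human") "human" else "machine",
                              video_id = as.character(vid))
    }
  }
  out
}

#' @rdname read_event_logs
#' @param log An `event_log`.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  df <- data.frame(video_id = log$video_id, source = log$source,
                   time_s = log$times, flag = 1L)
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop_io("cannot write event log: %s",
                                       conditionMessage(e)))
  invisible(path)
}
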