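#' Motion traces of true and predicted target positions
#'
#' A motion trace is a tibble with one row per imaging time point and columns
#' `fraction` (integer >= 1), `time_s` (seconds within the fraction), and the
#' x-ray imaged ("true") and tracking-predicted target positions in mm on the
#' (LR, AP, SI) axes: `true_lr`, `true_ap`, `true_si`, `pred_lr`, `pred_ap`,
#' `pred_si`. The per-point tracking error is `pred - true`; it is the only
#' quantity the coverage engine consumes.
#'
#' @param x A data frame with the columns above.
#' @return A `motion_trace` tibble.
#' @export
motion_trace <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(trace_columns(), names(x))
  if (length(missing) > 0) {
    stop(
      "missing trace column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[trace_columns()]
  if (nrow(x) == 0) stop("a motion trace must be non-empty", call. = FALSE)
  bad <- which(!apply(is.finite(as.matrix(x)), 1, all))
  if (length(bad) > 0) {
    stop(
      "non-finite coordinate in trace row(s): ",
      paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  x$fraction <- as.integer(x$fraction)
  ooo <- x |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_s)) |>
    dplyr::filter(!.data$ok)
  if (nrow(ooo) > 0) {
    stop(
      "time_s must be non-decreasing within fraction(s) ",
      paste(ooo$fraction, collapse = ", "),
      call. = FALSE
    )
  }
  class(x) <- c("motion_trace", class(tibble()))
  x
}

trace_columns <- function() {
  c(
    "fraction", "time_s",
    paste0("true_", .axis_names), paste0("pred_", .axis_names)
  )
}

#' @rdname motion_trace
#' @param trace A `motion_trace`.
#' @return `n_fractions()` returns the number of distinct fraction indices.
#' @export
n_fractions <- function(trace) length(unique(trace$fraction))

# N x 3 matrix of tracking-error vectors e = pred - true (mm), axes
# (LR, AP, SI).
trace_errors <- function(trace) {
  cbind(
    lr = trace$pred_lr - trace$true_lr,
    ap = trace$pred_ap - trace$true_ap,
    si = trace$pred_si - trace$true_si
  )
}

#' Read or write a motion trace CSV
#'
#' The CSV dialect is a comma-separated file with header
#' `fraction,time_s,true_lr,true_ap,true_si,pred_lr,pred_ap,pred_si`,
#' positions in mm, `.` decimal separator. Proprietary tracking-log formats
#' are out of scope; export logs to this dialect first.
#'
#' @param path CSV file path.
#' @param trace A `motion_trace` to write.
#' @return `read_trace()` returns a `motion_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                       progress = FALSE)
  motion_trace(x)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  readr::write_csv(trace, path)
  invisible(path)
}

#' Simulate a motion trace from per-axis tracking-error statistics
#'
#' True target positions follow a periodic breathing-like cosine path per
#' axis; predicted positions add independent per-axis Gaussian tracking
#' errors. The combined delivery error (correlation + prediction) is modelled
#' as a single Gaussian per axis, parameterized by its mean and SD in mm —
#' the form in which tracked lung cohorts report it (e.g. LR 1.21 +/- 0.81,
#' AP 0.58 +/- 0.31, SI 0.86 +/- 0.52 mm). Imaging time points are spaced
#' `dt_s` seconds apart within each fraction.
#'
#' @param sd Per-axis error SDs in mm, length 3, ordered (LR, AP, SI).
#' @param mean Per-axis error means in mm (default 0).
#' @param n_points_per_fraction Imaging time points per fraction (default 40).
#' @param n_fractions Number of treatment fractions (default 5).
#' @param amplitude Breathing-path amplitude per axis in mm (default SI-
#'   dominant `c(2, 2, 10)`); irrelevant to coverage, which depends only on
#'   `pred - true`, but kept for realism of the written traces.
#' @param period_s Breathing period in seconds (default 4).
#' @param dt_s Imaging interval in seconds (default 15).
#' @param seed Optional integer for reproducibility.
#' @return A `motion_trace` tibble.
#' @examples
#' tr <- simulate_trace(sd = c(1.21, 0.58, 0.86), seed = 1)
#' error_summary(tr)
#' @export
simulate_trace <- function(sd = c(1.21, 0.58, 0.86), mean = c(0, 0, 0),
                           n_points_per_fraction = 40, n_fractions = 5,
                           amplitude = c(2, 2, 10), period_s = 4, dt_s = 15,
                           seed = NULL) {
  sd <- rep_len(as.numeric(sd), 3L)
  mean <- rep_len(as.numeric(mean), 3L)
  amplitude <- rep_len(as.numeric(amplitude), 3L)
  if (any(sd < 0)) stop("error SDs must be >= 0", call. = FALSE)
  if (n_points_per_fraction < 1 || n_fractions < 1) {
    stop("need at least one point and one fraction", call. = FALSE)
  }
  gen <- function() {
    n <- n_points_per_fraction * n_fractions
    fraction <- rep(seq_len(n_fractions), each = n_points_per_fraction)
    time_s <- rep((seq_len(n_points_per_fraction) - 1) * dt_s, n_fractions)
    phase <- 2 * pi * time_s / period_s
    true <- matrix(0, n, 3)
    err <- matrix(0, n, 3)
    for (a in 1:3) {
      true[, a] <- amplitude[a] * cos(phase)
      err[, a] <- rnorm(n, mean[a], sd[a])
    }
    out <- tibble(
      fraction = fraction, time_s = time_s,
      true_lr = true[, 1], true_ap = true[, 2], true_si = true[, 3],
      pred_lr = true[, 1] + err[, 1],
      pred_ap = true[, 2] + err[, 2],
      pred_si = true[, 3] + err[, 3]
    )
    motion_trace(out)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Summarize tracking errors of a trace
#'
#' Per-axis moments of the signed error components `pred - true`, plus the
#' "total" row: moments of the per-point Euclidean error norm, the form in
#' which total correlation/prediction errors are usually quoted.
#'
#' @param trace A `motion_trace`.
#' @return A tibble with columns `axis` (`"lr"`, `"ap"`, `"si"`, `"total"`),
#'   `mean` and `sd` (mm).
#' @export
error_summary <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  e <- trace_errors(trace)
  nrm <- sqrt(rowSums(e^2))
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  tibble(
    axis = c(.axis_names, "total"),
    mean = unname(c(colMeans(e), mean(nrm))),
    sd = unname(c(apply(e, 2, sd0), sd0(nrm)))
  )
}
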