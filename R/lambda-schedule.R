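#' Lambda schedules for stratified alchemical sampling
#'
#' An alchemical path is discretized into windows by a grid of lambda
#' values.  The default grid has 20 windows at 0.05 spacing, i.e. lambda =
#' 0.00, 0.05, ..., 1.00 for a forward run; a backward schedule is the
#' exact reversal (1.00, 0.95, ..., 0.00).
#'
#' @param n_windows Number of windows (>= 1); the grid has
#'   `n_windows + 1` lambda values.
#' @param direction `"forward"` (0 to 1) or `"backward"` (1 to 0).
#' @return An object of class `lambda_schedule` with fields `values`
#'   (the lambda grid), `direction`, and `n_windows`.
#' @export
#' @examples
#' make_lambda_schedule(20, "forward")$values
make_lambda_schedule <- function(n_windows = 20L,
                                 direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!is.numeric(n_windows) || length(n_windows) != 1L ||
      !is.finite(n_windows) || n_windows < 1 || n_windows != round(n_windows)) {
    stop("'n_windows' must be a positive integer, got ", n_windows,
         call. = FALSE)
  }
  n_windows <- as.integer(n_windows)
  values <- seq(0, 1, length.out = n_windows + 1L)
  values[1L] <- 0; values[n_windows + 1L] <- 1 # exact endpoints
  if (direction == "backward") values <- rev(values)
  structure(
    list(values = values, direction = direction, n_windows = n_windows),
    class = "lambda_schedule"
  )
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("<lambda_schedule>", x$direction, "-", x$n_windows, "windows:",
      paste(utils::head(format(x$values, trim = TRUE), 4), collapse = ", "),
      "...\n")
  invisible(x)
}

validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  v <- schedule$values
  d <- diff(v)
  if (schedule$direction == "forward") {
    if (any(d <= 0)) stop("forward schedule must be strictly increasing")
    if (v[1] != 0 || v[length(v)] != 1) stop("schedule endpoints must be 0 and 1")
  } else {
    if (any(d >= 0)) stop("backward schedule must be strictly decreasing")
    if (v[1] != 1 || v[length(v)] != 0) stop("schedule endpoints must be 1 and 0")
  }
  invisible(schedule)
}

#' Construct one lambda window of energy-difference samples
#'
#' A window holds equilibrium samples of the energy difference
#' dU = H(x; lambda_to) - H(x; lambda_from) drawn at `lambda_from`.
#'
#' @param lambda_from,lambda_to Window end points, each in \[0, 1\].
#' @param samples_dU Finite energy-difference samples, kcal/mol.
#' @param T Temperature, Kelvin.
#' @param seed Integer seed the samples were drawn under (or `NA`).
#' @param n_equilibrated Number of post-burn-in samples; defaults to
#'   `length(samples_dU)`.
#' @return An object of class `fep_window`.
#' @export
fep_window <- function(lambda_from, lambda_to, samples_dU, T,
                       seed = NA_integer_,
                       n_equilibrated = length(samples_dU)) {
  assert_scalar_number(lambda_from, "lambda_from")
  assert_scalar_number(lambda_to, "lambda_to")
  if (lambda_from < 0 || lambda_from > 1 || lambda_to < 0 || lambda_to > 1) {
    stop("window lambda values must lie in [0, 1]", call. = FALSE)
  }
  assert_samples(samples_dU, "samples_dU")
  if (n_equilibrated < 1) stop("'n_equilibrated' must be >= 1", call. = FALSE)
  assert_scalar_number(T, "T", positive = TRUE)
  structure(
    list(lambda_from = lambda_from, lambda_to = lambda_to,
         samples_dU = as.numeric(samples_dU),
         n_equilibrated = as.integer(n_equilibrated),
         T = T, seed = seed),
    class = "fep_window"
  )
}

#' Assemble lambda windows into an FEP run
#'
#' Windows must tile the schedule without gaps (window j ends where window
#' j+1 starts) and share one temperature.
#'
#' @param windows List of [fep_window()] objects in path order.
#' @param direction `"forward"` or `"backward"`.
#' @param system Optional descriptor of the sampled system (a
#'   `toy_system` or a character label).
#' @return An object of class `fep_run`.
#' @export
fep_run <- function(windows, direction = c("forward", "backward"),
                    system = NULL) {
  direction <- match.arg(direction)
  if (!length(windows)) stop("an FEP run needs at least one window")
  stopifnot(all(vapply(windows, inherits, logical(1), "fep_window")))
  Ts <- vapply(windows, `[[`, numeric(1), "T")
  if (length(unique(Ts)) != 1L) {
    stop("all windows must share one temperature; got ",
         paste(unique(Ts), collapse = ", "))
  }
  from <- vapply(windows, `[[`, numeric(1), "lambda_from")
  to <- vapply(windows, `[[`, numeric(1), "lambda_to")
  if (length(windows) > 1L) {
    gaps <- abs(from[-1L] - to[-length(to)])
    if (any(gaps > 1e-12)) {
      stop("windows do not tile the schedule: gap after window ",
           which(gaps > 1e-12)[1L])
    }
  }
  step <- to - from
  if (direction == "forward" && any(step <= 0)) {
    stop("forward run must have strictly increasing lambda within windows")
  }
  if (direction == "backward" && any(step >= 0)) {
    stop("backward run must have strictly decreasing lambda within windows")
  }
  structure(
    list(windows = windows, direction = direction, system = system,
         T = Ts[1L]),
    class = "fep_run"
  )
}

#' @export
print.fep_run <- function(x, ...) {
  n <- vapply(x$windows, function(w) length(w$samples_dU), integer(1))
  cat("<fep_run>", x$direction, "-", length(x$windows), "windows, ",
      sum(n), "samples @", x$T, "K\n")
  invisible(x)
}

# lambda grid implied by a run's windows (from-values plus final to-value)
run_grid <- function(run) {
  from <- vapply(run$windows, `[[`, numeric(1), "lambda_from")
  c(from, run$windows[[length(run$windows)]]$lambda_to)
}
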