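#' Read per-window energy-difference files
#'
#' Two dialects are supported.
#'
#' **TSV dialect** (written by [write_windows()]): header line
#' `#T <kelvin>`, optional `#RUN <forward|backward>` section markers, then
#' for each window a `#WINDOW <lambda_from> <lambda_to>` line followed by
#' data rows `<step>\t<dU>` (dU in kcal/mol).  A file may carry several
#' runs separated by `#RUN` lines; [read_windows()] requires exactly one
#' run, [read_fep_runs()] returns all of them.
#'
#' **NAMD-style fepout dialect** (read-only): window boundaries are taken
#' from lines beginning `#NEW FEP WINDOW:` (the two lambda values on that
#' line), samples from lines beginning `FepEnergy:`, taking the dE column
#' (7th whitespace-separated field); remaining fields are not interpreted.
#' The temperature is read from the 9th field of the first sample line
#' unless supplied via `T`.
#'
#' Malformed data lines are collected and reported (with line numbers) as
#' a warning; a file yielding zero windows, or windows whose lambda
#' sequence is not monotone, is a format error.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"namd_fepout"`.
#' @param T Temperature override, Kelvin (required for fepout files that
#'   do not carry one).
#' @return [read_windows()]: a single [fep_run()]; [read_fep_runs()]: a
#'   list of runs.
#' @export
read_windows <- function(path, dialect = c("tsv", "namd_fepout"), T = NULL) {
  runs <- read_fep_runs(path, dialect = dialect, T = T)
  if (length(runs) != 1L) {
    stop(sprintf("expected a single run in '%s' but found %d; use read_fep_runs()",
                 path, length(runs)), call. = FALSE)
  }
  runs[[1L]]
}

#' @rdname read_windows
#' @export
read_fep_runs <- function(path, dialect = c("tsv", "namd_fepout"), T = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    parse_tsv_runs(lines, path)
  } else {
    list(parse_fepout_run(lines, path, T = T))
  }
}

# --- TSV dialect -----------------------------------------------------------

parse_tsv_runs <- function(lines, path) {
  T <- NA_real_
  bad <- integer(0)
  # sections[[k]] = list of windows; each window = list(from, to, steps, dU)
  runs_raw <- list()
  cur_windows <- list()
  cur_w <- NULL
  flush_window <- function() {
    if (!is.null(cur_w)) cur_windows[[length(cur_windows) + 1L]] <<- cur_w
    cur_w <<- NULL
  }
  flush_run <- function() {
    flush_window()
    if (length(cur_windows)) {
      runs_raw[[length(runs_raw) + 1L]] <<- cur_windows
    }
    cur_windows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#T")) {
      T <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]][2L]))
      if (is.na(T)) bad <- c(bad, i)
    } else if (startsWith(ln, "#RUN")) {
      flush_run()
    } else if (startsWith(ln, "#WINDOW")) {
      tok <- strsplit(ln, "\\s+")[[1L]]
      lam <- suppressWarnings(as.numeric(tok[2:3]))
      if (length(lam) != 2L || anyNA(lam)) {
        bad <- c(bad, i)
        next
      }
      flush_window()
      cur_w <- list(from = lam[1L], to = lam[2L], dU = numeric(0))
    } else if (startsWith(ln, "#")) {
      next # other comments ignored
    } else {
      tok <- strsplit(ln, "\t")[[1L]]
      du <- suppressWarnings(as.numeric(tok[2L]))
      if (is.null(cur_w) || length(tok) < 2L || is.na(du) || !is.finite(du)) {
        bad <- c(bad, i)
        next
      }
      cur_w$dU <- c(cur_w$dU, du)
    }
  }
  flush_run()
  if (length(bad)) {
    warning(sprintf("%s: %d malformed line(s) skipped (lines %s)", path,
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!length(runs_raw)) {
    stop(sprintf("format error in '%s': zero windows", path), call. = FALSE)
  }
  if (is.na(T)) {
    stop(sprintf("format error in '%s': missing '#T <kelvin>' header", path),
         call. = FALSE)
  }
  lapply(runs_raw, raw_windows_to_run, T = T, path = path)
}

raw_windows_to_run <- function(wlist, T, path) {
  from <- vapply(wlist, `[[`, numeric(1), "from")
  to <- vapply(wlist, `[[`, numeric(1), "to")
  step <- to - from
  if (all(step > 0)) {
    direction <- "forward"
  } else if (all(step < 0)) {
    direction <- "backward"
  } else {
    stop(sprintf("format error in '%s': non-monotone lambda sequence", path),
         call. = FALSE)
  }
  if (length(from) > 1L && any(diff(from) * step[1L] <= 0)) {
    stop(sprintf("format error in '%s': non-monotone lambda sequence", path),
         call. = FALSE)
  }
  windows <- lapply(wlist, function(w) {
    if (!length(w$dU)) {
      stop(sprintf("format error in '%s': window [%g, %g] has no samples",
                   path, w$from, w$to), call. = FALSE)
    }
    fep_window(w$from, w$to, w$dU, T = T)
  })
  fep_run(windows, direction = direction)
}

# --- NAMD-style fepout dialect ---------------------------------------------

parse_fepout_run <- function(lines, path, T = NULL) {
  bad <- integer(0)
  wlist <- list()
  cur_w <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "#NEW FEP WINDOW:")) {
      lam <- suppressWarnings(
        as.numeric(regmatches(ln, gregexpr("[0-9]*\\.?[0-9]+", ln))[[1L]]))
      lam <- lam[is.finite(lam) & lam >= 0 & lam <= 1]
      if (length(lam) < 2L) {
        bad <- c(bad, i)
        next
      }
      if (!is.null(cur_w)) wlist[[length(wlist) + 1L]] <- cur_w
      cur_w <- list(from = lam[1L], to = lam[2L], dU = numeric(0))
    } else if (startsWith(ln, "FepEnergy:")) {
      tok <- strsplit(ln, "\\s+")[[1L]]
      du <- suppressWarnings(as.numeric(tok[7L]))
      if (is.null(cur_w) || is.na(du) || !is.finite(du)) {
        bad <- c(bad, i)
        next
      }
      cur_w$dU <- c(cur_w$dU, du)
      if (is.null(T) && length(tok) >= 9L) {
        tguess <- suppressWarnings(as.numeric(tok[9L]))
        if (!is.na(tguess) && tguess > 0) T <- tguess
      }
    }
  }
  if (!is.null(cur_w)) wlist[[length(wlist) + 1L]] <- cur_w
  if (length(bad)) {
    warning(sprintf("%s: %d malformed line(s) skipped (lines %s)", path,
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!length(wlist)) {
    stop(sprintf("format error in '%s': zero windows", path), call. = FALSE)
  }
  if (is.null(T)) {
    stop(sprintf("'%s' carries no temperature; supply T explicitly", path),
         call. = FALSE)
  }
  raw_windows_to_run(wlist, T = T, path = path)
}

# --- writer ----------------------------------------------------------------

#' Write an FEP run (or run pair) to the TSV window dialect
#'
#' Inverse of [read_windows()] on the TSV dialect: deterministic,
#' bit-stable output (`%.17g` formatting round-trips doubles exactly).
#'
#' @param run An [fep_run()], or a list of runs (each written under its
#'   own `#RUN` section).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(run, path) {
  runs <- if (inherits(run, "fep_run")) list(run) else run
  stopifnot(all(vapply(runs, inherits, logical(1), "fep_run")))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(sprintf("#T %.17g", runs[[1L]]$T), con)
  for (r in runs) {
    writeLines(paste0("#RUN ", r$direction), con)
    for (w in r$windows) {
      writeLines(sprintf("#WINDOW %.17g %.17g", w$lambda_from, w$lambda_to),
                 con)
      writeLines(sprintf("%d\t%.17g", seq_along(w$samples_dU), w$samples_dU),
                 con)
    }
  }
  invisible(path)
}

#' Write a free-energy estimate as a JSON record
#'
#' Machine-readable result record with `value`, `stderr`, `method`, `T`,
#' and the per-window table.
#'
#' @param estimate A `free_energy_estimate`.
#' @param path Output JSON path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path = "") {
  stopifnot(inherits(estimate, "free_energy_estimate"))
  rec <- list(value = estimate$value, stderr = estimate$stderr,
              method = estimate$method, T = estimate$T,
              n_bootstrap = estimate$n_bootstrap,
              per_window = estimate$per_window)
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
  if (nzchar(path)) writeLines(json, path) else cat(json, "\n")
  invisible(path)
}
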