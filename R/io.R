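#' Read and write trial-series tables
#'
#' Trial series are stored as tab-delimited text with a header and columns
#' `participant`, `trial`, `phase`, `theta`, `reward`. The reward field
#' uses the explicit token `NA` on feedback-free trials (baseline,
#' washout), preserving the three-way outcome semantics rather than
#' collapsing "no feedback" onto failure. `write_trials()` /
#' `read_trials()` round-trip losslessly.
#'
#' @param series A trial-series data frame (one or several participants
#'   stacked).
#' @param path File path.
#' @return `read_trials()`: a `trial_series` data frame.
#'   `write_trials()`: the path, invisibly.
#' @export
write_trials <- function(series, path) {
  stopifnot(is.data.frame(series),
            all(c("participant", "trial", "phase", "theta", "reward")
                %in% names(series)))
  write.table(series[, c("participant", "trial", "phase", "theta", "reward")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c(participant = "character",
                                  trial = "integer", phase = "character",
                                  theta = "numeric", reward = "integer"))
  if (nrow(df) == 0L) {
    warning("empty trial file: ", path)
    class(df) <- c("trial_series", "data.frame")
    return(df)
  }
  ok_phase <- df$phase %in% c("baseline", "experimental", "washout")
  if (!all(ok_phase)) {
    bad <- which(!ok_phase)[1L]
    stop("unknown phase label '", df$phase[bad], "' at data line ", bad,
         " of ", path)
  }
  bad_reward <- !is.na(df$reward) & !df$reward %in% c(0L, 1L)
  if (any(bad_reward))
    stop("reward must be 0, 1 or NA; first bad value at data line ",
         which(bad_reward)[1L], " of ", path)
  class(df) <- c("trial_series", "data.frame")
  df
}

#' Generate an on-disk synthetic cohort fixture
#'
#' Simulates a cohort under the standard session protocol and writes the
#' trial table plus a JSON sidecar recording the generating configuration
#' (parameters, landscape, schedule, seed, package version). Deterministic
#' under `seed`: the same configuration writes byte-identical files.
#'
#' @param path Output path for the trial table; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param landscape A `"reward_landscape"`.
#' @param params A [model_params()].
#' @param schedule A [trial_schedule()].
#' @param n_individuals Number of simulated participants.
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @return Invisibly, a list with the `series` data frame and the sidecar
#'   `meta` list.
#' @export
generate_fixture <- function(path,
                             landscape = exp1_landscape("steep", "CW"),
                             params = model_params(),
                             schedule = trial_schedule(),
                             n_individuals = 40L,
                             seed = 1L) {
  stopifnot(is.numeric(seed))
  co <- simulate_cohort(params, landscape, schedule,
                        n = n_individuals, seed = as.integer(seed))
  phases <- schedule_phases(schedule)
  series <- do.call(rbind, lapply(seq_len(n_individuals), function(i)
    series_from_matrices(co$theta[i, ], co$reward[i, ], phases,
                         participant = i)))
  class(series) <- c("trial_series", "data.frame")
  write_trials(series, path)
  meta <- list(landscape = landscape$name,
               direction = landscape$direction,
               max_rate = landscape$max_rate,
               alpha = params$alpha,
               sigma_m = params$sigma_m,
               sigma_e = params$sigma_e,
               schedule = unclass(schedule)[c("n_baseline", "n_experimental",
                                              "n_washout")],
               n_individuals = as.integer(n_individuals),
               seed = as.integer(seed),
               package_version = as.character(utils::packageVersion("rewardscape")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(series = series, meta = meta))
}

#' Split a stacked trial table by participant
#'
#' @param series A trial-series data frame with a `participant` column.
#' @return Named list of single-participant `trial_series` data frames.
#' @export
split_participants <- function(series) {
  stopifnot(is.data.frame(series), "participant" %in% names(series))
  out <- split(series, series$participant)
  lapply(out, function(s) { class(s) <- c("trial_series", "data.frame"); s })
}
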