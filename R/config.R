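# Run configuration, profiles and report writers.
#
# Two profiles resolve all sampling sizes: `paper` preserves the published
# run counts (500 runs x 10,000 steps for conformational sampling; 100 runs
# x 2,000 steps for constrained binding sampling; 100-member initial
# stacks), `desk` is sized for interactive use and continuous testing on a
# single CPU. Every stochastic stage takes an explicit integer seed and the
# resolved configuration is part of the report, so any output can be
# reproduced exactly.

#' Default run configuration
#'
#' @param profile `"desk"` or `"paper"`
#' @return nested list of class `RunConfig`
#' @export
default_config <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    seeds = list(sampling = 1L, boltzmann = 1L, toy = 1L, titration = 1L),
    sampling = list(runs = 20L, steps_per_run = 500L, init_size = 10L,
                    capacity = 200L, diversity_radius = 0.5,
                    window = 15, cluster_radius = 1.0),
    boltzmann = list(runs = 10L, steps_per_run = 50L, tolerance = 1.0,
                     force_constant = 10, temperature = 300),
    descriptors = list(conversion = 0.025, hb_d_max = 3.5,
                       hb_angle_min = 120, sb_d_max = 4.0,
                       probe = 1.4, n_points = 960),
    anisotropy = list(pt = 250e-9, lst = 50e-9, kd1 = 13e-9,
                      replicates = 3L, sigma = 0.005),
    output_dir = ".")
  if (profile == "paper") {
    base$sampling$runs <- 500L
    base$sampling$steps_per_run <- 10000L
    base$sampling$init_size <- 100L
    base$boltzmann$runs <- 100L
    base$boltzmann$steps_per_run <- 2000L
  }
  structure(base, class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' Values are merged over the profile defaults; unknown keys are rejected
#' with the list of valid keys, so misspellings never pass silently.
#'
#' @param path YAML file (an empty file yields the full desk-profile
#'   defaults)
#' @return a `RunConfig`
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  profile <- user$profile %||% "desk"
  base <- default_config(profile)
  merge_checked <- function(base, user, prefix = "") {
    bad <- setdiff(names(user), names(base))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(prefix, bad, collapse = ", "),
           "; valid keys: ", paste0(prefix, names(base), collapse = ", "))
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && is.list(user[[nm]])) {
        base[[nm]] <- merge_checked(base[[nm]], user[[nm]],
                                    paste0(prefix, nm, "."))
      } else base[[nm]] <- user[[nm]]
    }
    base
  }
  out <- merge_checked(unclass(default_config(profile)), user)
  structure(out, class = "RunConfig")
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a result table or list in a stable format
#'
#' Output is byte-stable for identical inputs: keys sorted, floats in a
#' fixed 6-significant-digit format.
#'
#' @param results data.frame or named list
#' @param path output file
#' @param format `"json"`, `"csv"` or `"tsv"`
#' @return `path`, invisibly
#' @export
report <- function(results, path, format = c("json", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (is.data.frame(results)) {
      out <- results
    } else {
      out <- results[order(names(results))]
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(results))
    df <- results
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], .fmt_num)
    write.table(df, path, sep = if (format == "csv") "," else "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
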