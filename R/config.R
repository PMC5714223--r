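#' Read a flat key-value configuration file
#'
#' One \code{key value} pair per line (whitespace-separated); blank
#' lines and lines starting with \code{#} are ignored. Values that
#' parse as numbers are returned numeric.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    key <- parts[1]
    val <- paste(parts[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build a pipeline configuration from flat key-value settings
#'
#' Recognised keys: \code{iterations}, \code{alpha1}, \code{alpha2},
#' \code{alpha3}, \code{kappa}, \code{coincidence_cutoff}, \code{mode},
#' \code{threshold}, \code{consistency_min}. Unknown keys raise an
#' error. Settings override the shipped defaults; anything not named
#' keeps its default.
#'
#' @param settings Named list, e.g. from [read_config_file()].
#' @return A [homofold_config()].
#' @export
homofold_config_from <- function(settings) {
  known <- c("iterations", "alpha1", "alpha2", "alpha3", "kappa",
             "coincidence_cutoff", "mode", "threshold", "consistency_min")
  bad <- setdiff(names(settings), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  g <- function(key, default) if (!is.null(settings[[key]]))
    settings[[key]] else default
  mp <- default_match_params()
  homofold_config(
    iterations = g("iterations", 3L),
    match_params = match_score_params(g("alpha1", mp$alpha1),
                                      g("alpha2", mp$alpha2),
                                      g("alpha3", mp$alpha3)),
    kappa = g("kappa", 10),
    coincidence_cutoff = g("coincidence_cutoff", 0.01),
    mode = g("mode", "mea"),
    threshold = g("threshold", 0.5),
    consistency_min = g("consistency_min", 0.001))
}
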