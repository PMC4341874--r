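#' MIC frequency distribution
#'
#' Frequency distribution of minimum inhibitory concentrations for one
#' pathogen-drug combination, the denominator of the cumulative fraction of
#' response. MICs are treated as exact doubling-dilution values; frequencies
#' are normalised to sum to one.
#'
#' @param mic MIC values (mg/L), each > 0, no duplicates.
#' @param freq Frequencies or counts (>= 0, not all zero); normalised.
#' @param organism,agent Labels.
#' @param source Provenance string (origin and retrieval date).
#' @return An object of class `mic_distribution` with fields `mic`, `freq`
#'   (sorted by MIC), `organism`, `agent`, `source`.
#' @examples
#' mic_distribution(c(4, 2), c(1, 3))  # sorted: MIC 2 freq 0.75, MIC 4 freq 0.25
#' @export
mic_distribution <- function(mic, freq, organism = "", agent = "", source = "") {
  if (length(mic) == 0L) stop("empty MIC distribution", call. = FALSE)
  if (length(mic) != length(freq)) stop("'mic' and 'freq' lengths differ", call. = FALSE)
  if (!is.numeric(mic) || !is.numeric(freq) || anyNA(mic) || anyNA(freq)) {
    stop("'mic' and 'freq' must be numeric with no missing values", call. = FALSE)
  }
  if (any(mic <= 0)) stop("MIC values must be positive", call. = FALSE)
  if (anyDuplicated(mic)) stop("duplicate MIC values", call. = FALSE)
  if (any(freq < 0) || sum(freq) <= 0) {
    stop("'freq' must be non-negative with positive total", call. = FALSE)
  }
  keep <- freq > 0
  mic <- mic[keep]
  freq <- freq[keep]
  ord <- order(mic)
  structure(list(mic = mic[ord], freq = freq[ord] / sum(freq),
                 organism = organism, agent = agent, source = source),
            class = "mic_distribution")
}

#' @export
print.mic_distribution <- function(x, ...) {
  cat("MIC distribution", if (nzchar(x$organism)) paste0("(", x$organism,
      if (nzchar(x$agent)) paste0(" / ", x$agent), ")"), "\n")
  print(data.frame(mic_mg_L = x$mic, freq = round(x$freq, 6)), row.names = FALSE)
  if (nzchar(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}

#' Read an MIC frequency distribution from TSV
#'
#' Tab-separated file with a header and columns `mic_mg_L` plus either
#' `count` or `freq`; `#` lines are comments. A comment line of the form
#' `# organism: ...`, `# agent: ...` or `# source: ...` populates the
#' corresponding metadata field. Counts are normalised to frequencies and
#' zero-count rows dropped.
#'
#' @param path File path.
#' @return A [mic_distribution()] object.
#' @export
read_mic_distribution <- function(path) {
  if (!file.exists(path)) {
    stop("MIC distribution file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list(organism = "", agent = "", source = "")
  for (key in names(meta)) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(hit)) meta[[key]] <- trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("empty MIC distribution file: ", path, call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"mic_mg_L" %in% names(df)) {
    stop("missing 'mic_mg_L' column in ", path, call. = FALSE)
  }
  wcol <- intersect(c("count", "freq"), names(df))
  if (length(wcol) == 0L) {
    stop("need a 'count' or 'freq' column in ", path, call. = FALSE)
  }
  w <- df[[wcol[1]]]
  if (!is.numeric(df$mic_mg_L) || !is.numeric(w)) {
    stop("non-numeric values in ", path, call. = FALSE)
  }
  mic_distribution(df$mic_mg_L, w, organism = meta$organism,
                   agent = meta$agent, source = meta$source)
}

#' Write an MIC frequency distribution to TSV
#'
#' Writes metadata as `#` comment lines followed by `mic_mg_L` and `freq`
#' columns at full precision, so that `read_mic_distribution(write(...))`
#' round-trips exactly.
#'
#' @param dist A [mic_distribution()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mic_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "mic_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(dist$organism)) writeLines(paste("# organism:", dist$organism), con)
  if (nzchar(dist$agent)) writeLines(paste("# agent:", dist$agent), con)
  if (nzchar(dist$source)) writeLines(paste("# source:", dist$source), con)
  writeLines("mic_mg_L\tfreq", con)
  writeLines(paste(format(dist$mic, digits = 17, trim = TRUE, scientific = FALSE),
                   format(dist$freq, digits = 17, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Shipped wild-type MIC distribution snapshot
#'
#' Loads the packaged EUCAST-style wild-type *Pseudomonas aeruginosa*
#' piperacillin-tazobactam MIC frequency snapshot. The shipped file is a
#' synthetic stand-in constructed to match the published shape of that
#' distribution (mode at 4 mg/L, wild type up to 16 mg/L, a resistant tail);
#' it is not a download of the live EUCAST database (see the file's `source`
#' field).
#'
#' @return A [mic_distribution()] object.
#' @export
eucast_pa_piptaz <- function() {
  read_mic_distribution(system.file("extdata",
                                    "eucast_paeruginosa_piptaz_synthetic.tsv",
                                    package = "pippk", mustWork = TRUE))
}
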