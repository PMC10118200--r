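#' @keywords internal
"_PACKAGE"

# Coerce sex codes to a logical "is female" vector. Accepted codings:
# "F"/"M", "female"/"male" (any case), or 0/1 with 1 = female.
is_female <- function(sex) {
  if (is.logical(sex)) return(sex)
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1), na.rm = TRUE))
      stop("numeric sex must be coded 0 (male) / 1 (female)", call. = FALSE)
    return(sex == 1)
  }
  s <- toupper(as.character(sex))
  out <- rep(NA, length(s))
  out[s %in% c("F", "FEMALE")] <- TRUE
  out[s %in% c("M", "MALE")] <- FALSE
  if (anyNA(out[!is.na(s)]))
    stop("sex must be coded F/M (or female/male)", call. = FALSE)
  out
}

# Require that named columns are present and, for `positive` ones, finite
# and > 0. Used by the eGFR and risk-score front ends so a missing marker
# raises an explicit error instead of propagating NaN.
check_inputs <- function(x, needed, positive = needed, context = "input") {
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (nm in positive) {
    v <- x[[nm]]
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("%s: column '%s' must be present, finite and > 0 for all rows",
                   context, nm), call. = FALSE)
  }
  invisible(TRUE)
}

# Rolling polynomial hash of a character scalar modulo the Mersenne
# prime 2^31 - 1, returned as 8 hex digits. Used to stamp output files
# with a fingerprint of the run configuration (not cryptographic).
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Stable serialization of a config list for hashing.
config_hash <- function(config) {
  string_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE))
}

# Derive a child seed from a base seed and a stage label, staying < 2^31.
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 +
                strtoi(string_hash(stage), 16L)) %% 2147483647)
}

# Write a data.frame as CSV with a provenance comment header.
write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline
#'
#' Reads the comma-separated files written by [run_all()], skipping the
#' provenance comment line (`# config_hash=... seed=...`) they start with.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame`.
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
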