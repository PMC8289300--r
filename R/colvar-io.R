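# PLUMED-style whitespace text I/O: COLVAR (time, CV columns, bias) and
# HILLS (time, center, sigma, height[, biasf]) with '#! FIELDS' headers.

#' Read a PLUMED-style COLVAR file
#'
#' Whitespace-delimited numeric table with a `#! FIELDS time cv... bias`
#' header line naming the columns.
#'
#' @param path file path.
#' @return data.frame with the named columns.
#' @export
read_colvar <- function(path) read_plumed_table(path)

#' Read a PLUMED-style HILLS file
#'
#' @param path file path.
#' @return data.frame; columns are renamed to `time`, `center`, `sigma`,
#'   `height` (a trailing `biasf` column is kept if present).
#' @export
read_hills <- function(path) {
  df <- read_plumed_table(path)
  nm <- names(df)
  std <- c("time", "center", "sigma", "height")
  if (!all(std %in% nm)) {
    if (ncol(df) < 4) stop("HILLS file needs >= 4 columns: ", path)
    names(df)[1:4] <- std
  }
  df
}

read_plumed_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  dat <- lines[!startsWith(lines, "#")]
  dat <- dat[nzchar(trimws(dat))]
  if (!length(dat)) stop("no data rows in ", path)
  df <- read.table(text = dat, header = FALSE)
  if (length(hdr)) {
    cols <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "\\s+")[[1]]
    if (length(cols) == ncol(df)) names(df) <- cols
  }
  df
}

#' Write a PLUMED-style table (COLVAR or HILLS)
#'
#' @param df data.frame of numeric columns.
#' @param path output path.
#' @export
write_plumed_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  write.table(format(df, digits = 10, scientific = TRUE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a toy metadynamics run as COLVAR + HILLS text
#'
#' @param run a [sample_metad_double_well()] result.
#' @param colvar_path,hills_path output paths.
#' @param stride keep every `stride`-th frame in the COLVAR file.
#' @export
write_toyrun <- function(run, colvar_path, hills_path, stride = 10) {
  keep <- seq(1, length(run$time), by = stride)
  write_plumed_table(data.frame(time = run$time[keep], s = run$position[keep],
                                bias = run$bias[keep]), colvar_path)
  write_plumed_table(run$hills, hills_path)
  invisible(NULL)
}
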