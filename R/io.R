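# Reading deposited trial matrices (MAT 5.0) and CSV round-tripping of trial
# tables. The MAT reader is intentionally minimal: numeric (and logical)
# arrays in plain or zlib-compressed data elements, both endiannesses —
# enough for deposited behavioral matrices of the s1/s2/c form.

MAT_NUMERIC_TYPES <- c(`1` = "int8", `2` = "uint8", `3` = "int16", `4` = "uint16",
                       `5` = "int32", `6` = "uint32", `7` = "single", `9` = "double")

mat_decode_numeric <- function(type, data, endian) {
  switch(as.character(type),
    "1" = readBin(data, "integer", length(data), size = 1, signed = TRUE),
    "2" = readBin(data, "integer", length(data), size = 1, signed = FALSE),
    "3" = readBin(data, "integer", length(data) / 2, size = 2, signed = TRUE,
                  endian = endian),
    "4" = readBin(data, "integer", length(data) / 2, size = 2, signed = FALSE,
                  endian = endian),
    "5" = readBin(data, "integer", length(data) / 4, size = 4, endian = endian),
    "6" = {
      v <- readBin(data, "integer", length(data) / 4, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    "7" = readBin(data, "double", length(data) / 4, size = 4, endian = endian),
    "9" = readBin(data, "double", length(data) / 8, size = 8, endian = endian),
    stop("unsupported MAT data type ", type, call. = FALSE)
  )
}

# parse one data element starting at `pos` (1-based); returns type, raw data
# payload and the position after the (padded) element
mat_parse_element <- function(raw, pos, endian) {
  t32 <- readBin(raw[pos:(pos + 3L)], "integer", 1, size = 4, endian = endian)
  upper <- bitwAnd(bitwShiftR(t32, 16L), 0xFFFFL)
  if (upper != 0L) {  # small data element: size in upper half-word, 4 data bytes
    type <- bitwAnd(t32, 0xFFFFL)
    size <- upper
    data <- if (size > 0) raw[(pos + 4L):(pos + 3L + size)] else raw(0)
    list(type = type, size = size, data = data, next_pos = pos + 8L)
  } else {
    type <- t32
    size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4,
                    endian = endian)
    if (size < 0 || pos + 7L + size > length(raw))
      stop("malformed MAT element at byte ", pos, call. = FALSE)
    data <- if (size > 0) raw[(pos + 8L):(pos + 7L + size)] else raw(0)
    padded <- ceiling(size / 8) * 8
    list(type = type, size = size, data = data, next_pos = pos + 8L + padded)
  }
}

# decode a miMATRIX payload into list(name, value); value is NULL for
# non-numeric classes (cell/struct/char), which callers may skip
mat_parse_matrix <- function(data, endian) {
  pos <- 1L
  flags_el <- mat_parse_element(data, pos, endian)
  pos <- flags_el$next_pos
  flags <- readBin(flags_el$data[1:4], "integer", 1, size = 4, endian = endian)
  array_class <- bitwAnd(flags, 0xFFL)
  dims_el <- mat_parse_element(data, pos, endian)
  pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4, size = 4,
                  endian = endian)
  name_el <- mat_parse_element(data, pos, endian)
  pos <- name_el$next_pos
  name <- rawToChar(name_el$data)
  numeric_classes <- c(6, 7, 8, 9, 10, 11, 12, 13)  # double..uint32
  if (!(array_class %in% c(numeric_classes, 4)))  # 4 = char, decoded as numeric too
    return(list(name = name, value = NULL))
  real_el <- mat_parse_element(data, pos, endian)
  values <- mat_decode_numeric(real_el$type, real_el$data, endian)
  if (length(values) != prod(dims))
    stop("MAT variable `", name, "`: data length ", length(values),
         " does not match dimensions ", paste(dims, collapse = "x"), call. = FALSE)
  value <- if (length(dims) == 2 && dims[1] == 1 || length(dims) == 2 && dims[2] == 1)
    as.numeric(values)
  else
    array(as.numeric(values), dim = dims)
  list(name = name, value = value)
}

#' Read numeric variables from a MAT 5.0 file
#'
#' Minimal reader for Level 5 MAT-files: numeric and logical arrays, plain or
#' zlib-compressed elements, little- or big-endian. Character, cell and
#' struct variables are skipped with a message.
#'
#' @param path Path to the `.mat` file.
#' @return Named list of numeric vectors/matrices.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) stop("not a MAT 5.0 file (truncated header): ", path,
                              call. = FALSE)
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI") "big"
            else stop("not a MAT 5.0 file (bad endian indicator): ", path,
                      call. = FALSE)
  pos <- 129L
  vars <- list()
  while (pos + 7L <= length(raw)) {
    el <- mat_parse_element(raw, pos, endian)
    payload <- el
    if (el$type == 15L) {  # miCOMPRESSED: zlib stream wrapping one element
      # compressed elements are exempt from 8-byte padding
      pos <- pos + 8L + el$size
      inflated <- memDecompress(el$data, type = "gzip")
      payload <- mat_parse_element(inflated, 1L, endian)
    } else {
      pos <- el$next_pos
    }
    if (payload$type != 14L) next  # only miMATRIX elements carry variables
    m <- mat_parse_matrix(payload$data, endian)
    if (is.null(m$value)) {
      message("skipping non-numeric MAT variable `", m$name, "`")
      next
    }
    vars[[m$name]] <- m$value
  }
  vars
}

#' Decode a deposited trial-matrix file into a trial table
#'
#' Expects MAT 5.0 variables `s1`, `s2` (first/second stimulus in Hz) and `c`
#' (1 = correct), each N x 80 with one row per block. The interval holding
#' the reference is recovered as the tone equal to `reference_hz` (relative
#' tolerance `tol`), and the response is reconstructed from correctness and
#' which tone was higher. If the file carries an additional numeric vector of
#' length N it is taken as the participant identifier for each block (its
#' variable name is reported); otherwise each block is its own participant.
#'
#' @param path Path to the `.mat` file.
#' @param protocol_hint `"reference_lower"` or `"reference"`; recorded on the
#'   result and used for validation messages only.
#' @param reference_hz The constant reference frequency (default 1000).
#' @param tol Relative tolerance for reference detection (default 1e-6).
#' @return A trial table (see [simulate_experiment()] for the layout), with
#'   the protocol hint attached as attribute `"protocol"`.
#' @export
read_dataset_s1 <- function(path, protocol_hint = c("reference_lower", "reference"),
                            reference_hz = 1000, tol = 1e-6) {
  protocol_hint <- match.arg(protocol_hint)
  vars <- read_mat5(path)
  for (v in c("s1", "s2", "c"))
    if (is.null(vars[[v]]))
      stop("MAT file is missing required variable `", v, "`: ", path, call. = FALSE)
  s1 <- vars$s1; s2 <- vars$s2; cc <- vars$c
  if (!is.matrix(s1) || !is.matrix(s2) || !is.matrix(cc) ||
      !all(dim(s1) == dim(s2)) || !all(dim(s1) == dim(cc)))
    stop("s1/s2/c must be matrices of identical size", call. = FALSE)
  n_blocks <- nrow(s1)
  n_trials <- ncol(s1)
  extra <- setdiff(names(vars), c("s1", "s2", "c"))
  participant_of_block <- as.character(seq_len(n_blocks))
  for (v in extra) {
    if (is.null(dim(vars[[v]])) && length(vars[[v]]) == n_blocks) {
      message("using MAT variable `", v, "` (length ", n_blocks,
              ") as the participant identifier")
      participant_of_block <- as.character(vars[[v]])
      break
    }
  }
  rows <- vector("list", n_blocks)
  block_counter <- stats::setNames(rep(0L, length(unique(participant_of_block))),
                                   unique(participant_of_block))
  for (i in seq_len(n_blocks)) {
    pid <- participant_of_block[i]
    block_counter[pid] <- block_counter[pid] + 1L
    f1 <- s1[i, ]; f2 <- s2[i, ]
    if (any(f1 <= 0) || any(f2 <= 0))
      stop("non-positive stimulus frequency in block ", i, call. = FALSE)
    ref1 <- abs(f1 - reference_hz) / reference_hz < tol
    ref2 <- abs(f2 - reference_hz) / reference_hz < tol
    bad <- !(ref1 | ref2)
    if (any(bad))
      stop("block ", i, ", trial(s) ", paste(which(bad), collapse = ", "),
           ": neither tone equals the ", reference_hz, " Hz reference", call. = FALSE)
    correct <- cc[i, ] == 1
    rows[[i]] <- data.frame(
      participant = pid, block = unname(block_counter[pid]),
      trial = seq_len(n_trials),
      x1 = log(f1), x2 = log(f2), ref_hz = reference_hz,
      ref_position = ifelse(ref1, "first", "second"),
      diff_percent = 100 * abs(f2 - f1) / reference_hz,
      response_first_higher = correct == (f1 > f2),
      correct = correct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "protocol") <- protocol_hint
  out
}

TRIAL_TABLE_COLUMNS <- c("participant", "block", "trial", "f1_hz", "f2_hz",
                         "ref_hz", "ref_position", "diff_percent",
                         "response_first_higher", "correct")

#' Write a trial table to CSV
#'
#' Serializes with a fixed header and frequencies in Hz printed with 17
#' significant digits (exact double round trip), in the table's row order.
#'
#' @param tab A trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(tab, path) {
  full <- function(x) {  # shortest exact decimal representation (17 sig. digits)
    out <- sprintf("%.17g", as.numeric(x))
    out[is.na(x)] <- NA_character_
    out
  }
  out <- data.frame(
    participant = tab$participant, block = tab$block, trial = tab$trial,
    f1_hz = full(if (!is.null(tab$f1_hz)) tab$f1_hz else exp(tab$x1)),
    f2_hz = full(if (!is.null(tab$f2_hz)) tab$f2_hz else exp(tab$x2)),
    ref_hz = full(tab$ref_hz), ref_position = tab$ref_position,
    diff_percent = full(if (!is.null(tab$diff_percent)) tab$diff_percent
                        else NA_real_),
    response_first_higher = tab$response_first_higher, correct = tab$correct,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Inverse of [write_trial_table()]: restores the internal log-frequency
#' columns (`x1`, `x2`) alongside the serialized Hz columns.
#'
#' @param path CSV file path.
#' @return A trial table.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(
    path, stringsAsFactors = FALSE,
    colClasses = c(participant = "character", block = "integer",
                   trial = "integer", f1_hz = "numeric", f2_hz = "numeric",
                   ref_hz = "numeric", ref_position = "character",
                   diff_percent = "numeric",
                   response_first_higher = "logical", correct = "logical"))
  missing_cols <- setdiff(TRIAL_TABLE_COLUMNS, names(tab))
  if (length(missing_cols) > 0)
    stop("trial table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$x1 <- log(tab$f1_hz)
  tab$x2 <- log(tab$f2_hz)
  tab$participant <- as.character(tab$participant)
  tab
}
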