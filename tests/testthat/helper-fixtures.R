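# Builders for small deterministic fixtures, constructed in code at test time.

# a block data frame from explicit tone frequencies (Hz) and outcomes
make_block <- function(f1_hz, f2_hz, correct = NULL, response_first_higher = NULL,
                       ref_hz = 1000, ref_position = NULL,
                       participant = "p1", block = 1L) {
  n <- length(f1_hz)
  stopifnot(length(f2_hz) == n)
  if (is.null(response_first_higher)) {
    stopifnot(!is.null(correct))
    response_first_higher <- correct == (f1_hz > f2_hz)
  }
  if (is.null(correct)) correct <- response_first_higher == (f1_hz > f2_hz)
  if (is.null(ref_position))
    ref_position <- ifelse(abs(f1_hz - ref_hz) < 1e-9, "first",
                           ifelse(abs(f2_hz - ref_hz) < 1e-9, "second", "none"))
  data.frame(participant = participant, block = block, trial = seq_len(n),
             x1 = log(f1_hz), x2 = log(f2_hz), ref_hz = ref_hz,
             ref_position = ref_position,
             diff_percent = 100 * abs(f2_hz - f1_hz) / ref_hz,
             response_first_higher = response_first_higher,
             correct = correct, stringsAsFactors = FALSE)
}

# minimal MAT 5.0 writer (uncompressed, little-endian, double arrays only),
# used to build synthetic .mat fixtures for exercising the reader
write_mat5_synthetic <- function(path, vars) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw("MATLAB 5.0 MAT-file, synthetic test fixture")
  writeBin(c(desc, rep(as.raw(0x20), 116 - length(desc))), con)
  writeBin(rep(as.raw(0), 8), con)                      # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                  # version 0x0100
  writeBin(charToRaw("IM"), con)                        # little-endian marker
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- if (is.matrix(v)) dim(v) else c(1L, length(v))
    values <- as.double(v)                              # column-major
    name_raw <- charToRaw(nm)
    name_pad <- (8 - length(name_raw) %% 8) %% 8
    body_len <- 16L + 16L + (8L + length(name_raw) + name_pad) +
      (8L + 8L * length(values))
    writeBin(as.integer(c(14L, body_len)), con, size = 4, endian = "little")
    writeBin(as.integer(c(6L, 8L, 6L, 0L)), con, size = 4, endian = "little")
    writeBin(as.integer(c(5L, 8L, dims[1], dims[2])), con, size = 4,
             endian = "little")
    writeBin(as.integer(c(1L, length(name_raw))), con, size = 4,
             endian = "little")
    writeBin(name_raw, con)
    if (name_pad > 0) writeBin(rep(as.raw(0), name_pad), con)
    writeBin(as.integer(c(9L, 8L * length(values))), con, size = 4,
             endian = "little")
    writeBin(values, con, size = 8, endian = "little")
  }
  invisible(path)
}

# s1/s2/c matrices for a synthetic reference-containing dataset: each block's
# non-reference tone is a fixed percent above or below the reference, with a
# known correctness pattern
synthetic_dataset_matrices <- function(n_blocks = 4, n_trials = 12, seed = 100) {
  set.seed(seed)
  s1 <- s2 <- cc <- matrix(0, n_blocks, n_trials)
  for (i in seq_len(n_blocks)) {
    ref_first <- runif(n_trials) < 0.5
    nonref <- 1000 * (1 + runif(n_trials, 0.01, 0.2))
    s1[i, ] <- ifelse(ref_first, 1000, nonref)
    s2[i, ] <- ifelse(ref_first, nonref, 1000)
    cc[i, ] <- as.double(runif(n_trials) < 0.8)
  }
  list(s1 = s1, s2 = s2, c = cc)
}
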