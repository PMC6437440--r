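# Minimal FCS 3.0/3.1 support.  List-mode files with DATATYPE F (float32),
# D (float64) or I (byte-aligned unsigned integers); channel names taken
# from $PnS, falling back to $PnN.

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode files with floating-point (`$DATATYPE F`/`D`) or
#' byte-aligned integer (`I`) data, little- or big-endian. Channel
#' (species) names come from `$PnS`, falling back to `$PnN`.
#'
#' @param path FCS file.
#' @param channels optional include-list of channel names.
#' @return A [cell_matrix()].
#' @export
read_fcs <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (nchar(header) < 58) stop("parse error: ", path, " is not an FCS file (truncated header)")
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1", "FCS2.0"))
    stop("parse error at byte 0: unsupported FCS version '", version, "'")
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  seek(con, text_start)
  txt <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("parse error in TEXT segment of ", path)
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, toupper(trimws(keys)))
  need <- function(k) {
    if (!k %in% names(kw)) stop("parse error: missing keyword ", k, " in ", path)
    kw[[k]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (toupper(need("$MODE")) != "L") stop("only list-mode ($MODE L) FCS files are supported")
  if (data_start == 0 && "$BEGINDATA" %in% names(kw))
    data_start <- as.numeric(kw[["$BEGINDATA"]])
  get_kw <- function(k) {
    v <- unname(kw[k])
    if (length(v) == 0 || is.na(v)) NA_character_ else v
  }
  pnn <- vapply(seq_len(n_par), function(p) {
    v <- get_kw(paste0("$P", p, "N"))
    if (is.na(v)) paste0("P", p) else v
  }, character(1))
  pns <- vapply(seq_len(n_par), function(p) {
    s <- get_kw(paste0("$P", p, "S"))
    if (is.na(s) || !nzchar(trimws(s))) NA_character_ else s
  }, character(1))
  nm <- ifelse(is.na(pns), pnn, pns)
  seek(con, data_start)
  n_values <- n_par * n_tot
  if (dtype == "F") {
    v <- readBin(con, "numeric", n = n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    v <- readBin(con, "numeric", n = n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    bits <- as.integer(get_kw("$P1B"))
    if (is.na(bits) || bits %% 8 != 0) stop("unsupported $PnB for integer data")
    v <- readBin(con, "integer", n = n_values, size = bits / 8,
                 signed = FALSE, endian = endian)
  } else stop("unsupported $DATATYPE '", dtype, "'")
  if (length(v) < n_values)
    stop("parse error: DATA segment of ", path, " is truncated")
  m <- matrix(v, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(m) <- nm
  if (!is.null(channels)) {
    missing <- setdiff(channels, nm)
    if (length(missing))
      stop("channels not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(nm, collapse = ", "))
    m <- m[, channels, drop = FALSE]
  }
  cell_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a matrix as a minimal FCS 3.0 file
#'
#' List-mode, float32, little-endian. Intended for constructing small
#' round-trip test files and for interoperability with cytometry tools;
#' not a full-featured FCS writer.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(x, path) {
  v <- .values(x)
  n <- nrow(v); p <- ncol(v)
  nm <- colnames(v)
  if (is.null(nm)) nm <- paste0("P", seq_len(p))
  d <- "|"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", p, "$TOT", n, "$NEXTDATA", "0")
  for (i in seq_len(p))
    kv <- c(kv, paste0("$P", i, "N"), nm[i], paste0("$P", i, "S"), nm[i],
            paste0("$P", i, "B"), 32, paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), 262144)
  text <- paste0(d, paste(kv, collapse = d), d)
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n * p - 1
  pad <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad(text_start), pad(text_end),
                   pad(data_start), pad(data_end), pad(0), pad(0))
  stopifnot(nchar(header) == 58)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  invisible(path)
}
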