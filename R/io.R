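# Readers and writers for the interchange formats: TSV event tables with
# provenance comment lines, line-oriented contour text blocks, PGM image
# patches and key=value configuration files.

#' Read a per-event feature table
#'
#' Tab-separated values with a header row; lines starting with `#` carry
#' provenance (seed, configuration) and are ignored on read. Feature
#' columns must be numeric; metadata columns (`event`, `roi`, `replicate`,
#' `condition`) are kept as character.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop("no header line in ", path, call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header)) stop("duplicate column names", call. = FALSE)
  ncol <- length(header)
  meta_cols <- c("event", "roi", "replicate", "condition")
  rows <- lapply(seq_along(body)[-1L], function(i) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != ncol) {
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   i, path, length(parts), ncol), call. = FALSE)
    }
    parts
  })
  cols <- lapply(seq_len(ncol), function(j) {
    vals <- vapply(rows, `[[`, character(1), j)
    if (header[j] %in% meta_cols) return(vals)
    num <- suppressWarnings(as.numeric(vals))
    parse_failed <- is.na(num) & !(vals %in% c("NA", ""))
    if (!any(parse_failed)) return(num)
    # fully non-numeric columns are carried as character metadata; a mix
    # of numeric and non-numeric cells in one column is a data error
    if (all(parse_failed | vals %in% c("NA", ""))) return(vals)
    bad <- which(parse_failed)
    stop(sprintf("non-numeric value '%s' in column `%s`, data row %d",
                 vals[bad[1L]], header[j], bad[1L]), call. = FALSE)
  })
  names(cols) <- header
  tibble::as_tibble(cols)
}

#' Write a per-event feature table
#'
#' Writes a TSV with provenance comment lines (`# seed=...`,
#' `# config-hash=...`) ahead of the header. Numeric values are printed
#' with 9 significant digits so write/read round trips are stable.
#'
#' @param data Data frame to write.
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance block.
#' @param config Optional named list recorded as a config hash.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(data, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  writeLines(sprintf("# config-hash=%s", config_hash(config)), con)
  fmt <- function(x) {
    if (is.logical(x)) return(as.character(as.integer(x)))
    if (is.numeric(x)) sprintf("%.9g", x) else as.character(x)
  }
  writeLines(paste(names(data), collapse = "\t"), con)
  cols <- lapply(data, fmt)
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (length(lines) > 0L) writeLines(lines, con)
  invisible(path)
}

# stable short hash of a key=value configuration (polynomial rolling hash
# over the serialized text, modulo 2^31 - 1); "none" for NULL
config_hash <- function(config) {
  if (is.null(config) || length(config) == 0L) return("none")
  txt <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 7
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read contours from the line-oriented text format
#'
#' One event per block: a header `#event <id> pixel_size=<float>` followed
#' by one `x<TAB>y` coordinate pair per line; a blank line (or end of file)
#' terminates the block.
#'
#' @param path File path.
#' @return A named list of [contour()] objects (names = event ids).
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  id <- NULL; ps <- 1; xs <- numeric(0); ys <- numeric(0)
  flush_block <- function() {
    if (is.null(id)) return(invisible())
    if (length(xs) < 3L) {
      stop(sprintf("event '%s' has fewer than 3 contour points", id),
           call. = FALSE)
    }
    out[[id]] <<- contour(xs, ys, pixel_size = ps, id = id)
    id <<- NULL; xs <<- numeric(0); ys <<- numeric(0)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush_block(); next }
    if (startsWith(ln, "#event")) {
      flush_block()
      m <- regmatches(ln, regexec(
        "^#event\\s+(\\S+)\\s+pixel_size=([0-9.eE+-]+)\\s*$", ln))[[1L]]
      if (length(m) != 3L) stop("malformed contour header: ", ln, call. = FALSE)
      id <- m[2L]; ps <- as.numeric(m[3L])
      next
    }
    if (is.null(id)) {
      stop("contour coordinates before any #event header", call. = FALSE)
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || any(is.na(vals))) {
      stop(sprintf("malformed coordinate line in event '%s': %s", id, ln),
           call. = FALSE)
    }
    xs <- c(xs, vals[1L]); ys <- c(ys, vals[2L])
  }
  flush_block()
  out
}

#' Write contours to the line-oriented text format
#'
#' @param contours A list of [contour()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (is_contour(contours)) contours <- list(contours)
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in contours) {
    assert_contour(ct)
    id <- attr(ct, "id")
    if (is.na(id)) id <- "event"
    writeLines(sprintf("#event %s pixel_size=%.9g", id,
                       contour_pixel_size(ct)), con)
    writeLines(paste(sprintf("%.9g", ct$x), sprintf("%.9g", ct$y),
                     sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a PGM image patch
#'
#' Supports binary (`P5`, 8-bit) and ASCII (`P2`) portable graymaps.
#'
#' @param path File path.
#' @param origin Pixel coordinates of the first pixel center.
#' @return An [image_patch()].
#' @export
read_pgm <- function(path, origin = c(0, 0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    vals <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else {
    vals <- matrix(vapply(seq_len(w * h), function(i) as.integer(tok()),
                          integer(1)), nrow = h, ncol = w, byrow = TRUE)
  }
  image_patch(vals, origin = origin, max_value = mx)
}

# whitespace/comment-aware token reader for PGM headers
pgm_tokenizer <- function(con) {
  function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) {
        if (nzchar(tok)) return(tok)
        stop("unexpected end of PGM header", call. = FALSE)
      }
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("\\s", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
}

#' Write an image patch as PGM
#'
#' @param patch An [image_patch()].
#' @param path Output path.
#' @param ascii Write ASCII `P2` instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(patch, path, ascii = FALSE) {
  stopifnot(inherits(patch, "rtdc_patch"))
  v <- patch$values
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(v), nrow(v)),
                 as.character(patch$max_value)), con)
    writeLines(apply(v, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(v), nrow(v), patch$max_value),
              con, eos = NULL)
    writeBin(as.integer(t(v)), con, size = 1L)
  }
  invisible(path)
}

#' Read a key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
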