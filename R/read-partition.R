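#' Parse a Bismark-style per-base methylation call string
#'
#' The call string encodes one character per base: `Z`/`z` methylated and
#' unmethylated CpG, `X`/`x` CHG, `H`/`h` CHH, `U`/`u` unknown context, and
#' `.` for non-cytosine positions. CHG and CHH are pooled into the CH
#' context; `U`/`u` and `.` are ignored.
#'
#' @param call_string A single string over the alphabet `Zz Xx Hh Uu .`.
#' @param read_id Optional read identifier carried into the result.
#'
#' @return A one-row tibble with columns `read_id`, `mch`, `ch`, `mcg`, `cg`.
#' @export
#'
#' @examples
#' parse_methylation_call_string("HHHhh")  # mch 3 of ch 5
parse_methylation_call_string <- function(call_string, read_id = NA_character_) {
  stopifnot(is.character(call_string), length(call_string) == 1L)
  chars <- strsplit(call_string, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("Z", "z", "X", "x", "H", "h", "U", "u", "."))
  if (length(bad) > 0) {
    mf_abort(
      sprintf("Invalid methylation call symbol '%s' at position %d.",
              chars[bad[1]], bad[1]),
      "parse_error"
    )
  }
  n <- function(code) sum(chars == code)
  mch <- n("X") + n("H")
  mcg <- n("Z")
  tibble::tibble(
    read_id = read_id,
    mch = mch, ch = mch + n("x") + n("h"),
    mcg = mcg, cg = mcg + n("z")
  )
}

#' Thresholds for RNA/DNA read classification
#'
#' Reads with enough informative cytosines are called DNA when their mCH
#' ratio is strictly below `dna_max_ratio` and RNA when strictly above
#' `rna_min_ratio`; everything else (including reads with fewer than
#' `min_cytosines` CH positions) is ambiguous.
#'
#' @param dna_max_ratio,rna_min_ratio Strict ratio bounds (defaults 0.5, 0.9).
#' @param min_cytosines Minimum CH cytosines per read (default 3).
#' @return A list of class `partition_thresholds`.
#' @export
partition_thresholds <- function(dna_max_ratio = 0.5, rna_min_ratio = 0.9,
                                 min_cytosines = 3L) {
  assert_scalar_number(dna_max_ratio, "dna_max_ratio", 0, 1)
  assert_scalar_number(rna_min_ratio, "rna_min_ratio", 0, 1)
  assert_count(min_cytosines, "min_cytosines")
  if (dna_max_ratio >= rna_min_ratio) {
    mf_abort("`dna_max_ratio` must be below `rna_min_ratio`.", "bad_argument")
  }
  structure(list(dna_max_ratio = dna_max_ratio,
                 rna_min_ratio = rna_min_ratio,
                 min_cytosines = as.integer(min_cytosines)),
            class = "partition_thresholds")
}

#' Classify reads as DNA, RNA or ambiguous by read-level mCH
#'
#' Vectorized over reads. A read with `ch = 0` or fewer than
#' `min_cytosines` CH calls is ambiguous; boundary ratios exactly at a
#' threshold are ambiguous because the inequalities are strict.
#'
#' @param mch,ch Methylated and total CH call counts (vectors).
#' @param thresholds A [partition_thresholds].
#' @return Character vector over `{"DNA", "RNA", "ambiguous"}`.
#' @export
#'
#' @examples
#' classify_read(c(10, 0, 1), c(10, 10, 2))
classify_read <- function(mch, ch, thresholds = partition_thresholds()) {
  stopifnot(length(mch) == length(ch))
  if (any(mch > ch, na.rm = TRUE) || any(mch < 0 | ch < 0, na.rm = TRUE)) {
    mf_abort("Need 0 <= mch <= ch.", "bad_argument")
  }
  out <- rep("ambiguous", length(mch))
  informative <- ch >= thresholds$min_cytosines
  ratio <- ifelse(ch > 0, mch / ch, NA_real_)
  out[informative & ratio < thresholds$dna_max_ratio] <- "DNA"
  out[informative & ratio > thresholds$rna_min_ratio] <- "RNA"
  out
}

#' Partition a table of reads into DNA/RNA/ambiguous bins
#'
#' @param records Data frame with columns `mch`, `ch` (and optionally
#'   `read_id`), e.g. from [generate_reads()] or
#'   [parse_methylation_call_string()].
#' @param thresholds A [partition_thresholds].
#'
#' @return A list of class `read_partition` with `summary` (tibble of class,
#'   n, fraction) and `read_ids` (named list of per-class read-id vectors).
#' @export
partition_reads <- function(records, thresholds = partition_thresholds()) {
  records <- tibble::as_tibble(records)
  n_reads <- nrow(records)
  cls <- if (n_reads > 0) classify_read(records$mch, records$ch, thresholds)
         else character(0)
  lev <- c("DNA", "RNA", "ambiguous")
  counts <- table(factor(cls, levels = lev))
  ids <- if ("read_id" %in% names(records)) records$read_id
         else as.character(seq_len(n_reads))
  structure(
    list(
      summary = tibble::tibble(
        class = lev,
        n = as.integer(counts),
        fraction = if (n_reads > 0) as.integer(counts) / n_reads
                   else rep(0, 3)
      ),
      read_ids = split(ids, factor(cls, levels = lev)),
      thresholds = thresholds
    ),
    class = "read_partition"
  )
}

#' @export
print.read_partition <- function(x, ...) {
  cat("<read_partition>\n")
  print(x$summary)
  invisible(x)
}

#' Read per-read methylation records from a SAM file with XM-style tags
#'
#' A convenience reader for plain-text SAM: extracts the `XM:Z:` tag from
#' each alignment line and parses it with
#' [parse_methylation_call_string()]. Alignment itself is out of scope; the
#' canonical input for this module is a TSV of per-read counts.
#'
#' @param path Path to a SAM file.
#' @return A tibble with one row per read carrying an XM tag.
#' @export
read_sam_methylation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  recs <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    xm <- grep("^XM:Z:", fields, value = TRUE)
    if (length(xm) == 0) return(NULL)
    parse_methylation_call_string(sub("^XM:Z:", "", xm[1]),
                                  read_id = fields[1])
  })
  dplyr::bind_rows(recs)
}
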