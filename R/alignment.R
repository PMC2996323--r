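BASES <- c("A", "C", "G", "T")

#' Encode/decode nucleotides as integer states
#'
#' The integer coding used throughout the package: A=0, C=1, G=2, T=3, and
#' -1 for gaps or ambiguity codes (which are treated as missing data and
#' projected out of all likelihoods).
#'
#' @param x Character vector of bases (`encode_bases`) or integer states
#'   (`decode_bases`).
#' @param gap Character used for missing states when decoding.
#' @return Integer states, or a character vector of bases.
#' @export
encode_bases <- function(x) {
  i <- match(toupper(x), BASES)
  ifelse(is.na(i), -1L, i - 1L)
}

#' @rdname encode_bases
#' @export
decode_bases <- function(x, gap = "-") {
  out <- rep(gap, length(x))
  ok <- x >= 0
  out[ok] <- BASES[x[ok] + 1L]
  out
}

#' Reference-projected alignment
#'
#' Container for a multiple alignment compressed to the coordinates of a
#' designated reference species: columns where the reference carries a gap
#' are removed, so each remaining column maps to one reference position.
#'
#' @param states Integer matrix, species x positions, with values 0..3
#'   (A, C, G, T) or -1 (gap or ambiguous).  Row names are species names.
#' @param reference Name of the reference species (must be a row and never
#'   -1).
#' @param positions 0-based reference coordinates of the columns, strictly
#'   increasing.
#' @param chrom Chromosome/contig name of the reference.
#' @return An object of class `"ref_alignment"`.
#' @export
ref_alignment <- function(states, reference, positions = NULL, chrom = "chr1") {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  storage.mode(states) <- "integer"
  if (!reference %in% rownames(states))
    stop("reference species '", reference, "' not among alignment rows")
  if (is.null(positions)) positions <- seq_len(ncol(states)) - 1L
  positions <- as.integer(positions)
  if (length(positions) != ncol(states))
    stop("positions must have one entry per column")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (any(states[reference, ] < 0))
    stop("reference row contains gaps; reference-gap columns must be removed")
  structure(list(states = states, reference = reference,
                 positions = positions, chrom = chrom),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat("Reference-projected alignment:", nrow(x$states), "species x",
      ncol(x$states), "columns\n")
  cat("  reference:", x$reference, " chrom:", x$chrom, "\n")
  if (ncol(x$states))
    cat("  reference span: [", min(x$positions), ",", max(x$positions) + 1L,
        ")\n")
  invisible(x)
}

maf_species <- function(src) sub("\\..*$", "", src)

#' Read a MAF alignment, projected to reference coordinates
#'
#' Parses a Multiple Alignment Format file and compresses it to the reference:
#' columns where the reference row has a gap are dropped, species absent from
#' a block are gapped across that block, and blocks overlapping on the
#' reference are resolved first-block-wins (with a warning).  Blocks missing
#' the reference row are skipped with a warning.
#'
#' MAF `s` lines name sequences as `species.contig`; the species is the part
#' before the first dot.  Sequence text is used as oriented in the file.
#'
#' @param path Path to a MAF file.
#' @param reference Reference species name.
#' @return A [ref_alignment()]; empty input yields a 0-column alignment.
#' @export
read_maf <- function(path, reference) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      blocks <- flush(cur, blocks)
      cur <- character()
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop("malformed MAF: 's' line before any 'a' line")
      cur <- c(cur, ln)
    } else if (grepl("^\\s*$", ln) || grepl("^[ieq] ", ln)) {
      # blank and i/e/q lines ignored
    } else {
      stop("malformed MAF line: ", substr(ln, 1, 60))
    }
  }
  blocks <- flush(cur, blocks)

  cols <- list(); poss <- list(); chrom <- "chr1"
  all_species <- character()
  for (bi in seq_along(blocks)) {
    rows <- strsplit(blocks[[bi]], "[ \t]+")
    bad <- vapply(rows, length, 1L) < 7L
    if (any(bad)) stop("malformed MAF 's' line in block ", bi)
    src <- vapply(rows, `[[`, "", 2L)
    start <- as.integer(vapply(rows, `[[`, "", 3L))
    text <- toupper(vapply(rows, function(r) r[[length(r)]], ""))
    sp <- maf_species(src)
    if (anyDuplicated(sp))
      stop("duplicate species in MAF block ", bi)
    iref <- match(reference, sp)
    if (is.na(iref)) {
      warning("MAF block ", bi, " has no reference row; skipped")
      next
    }
    if (length(unique(nchar(text))) != 1)
      stop("malformed MAF: unequal row lengths in block ", bi)
    chars <- do.call(rbind, strsplit(text, ""))
    rownames(chars) <- sp
    refrow <- chars[iref, ]
    keep <- refrow != "-"
    if (!any(keep)) next
    pos <- start[iref] + cumsum(keep) - 1L
    st <- matrix(encode_bases(chars[, keep, drop = FALSE]),
                 nrow = nrow(chars), dimnames = list(sp, NULL))
    cols[[length(cols) + 1L]] <- st
    poss[[length(poss) + 1L]] <- pos[keep]
    chrom <- sub("^[^.]*\\.", "", src[iref])
    all_species <- union(all_species, sp)
  }
  if (!length(cols)) {
    st <- matrix(integer(), nrow = max(1L, length(reference)), ncol = 0,
                 dimnames = list(reference, NULL))
    return(ref_alignment(st, reference, integer(), chrom))
  }
  npos <- sum(vapply(poss, length, 1L))
  states <- matrix(-1L, nrow = length(all_species), ncol = npos,
                   dimnames = list(all_species, NULL))
  positions <- integer(npos)
  seen <- new.env(hash = TRUE)
  at <- 0L
  dropped <- 0L
  for (i in seq_along(cols)) {
    p <- poss[[i]]
    key <- as.character(p)
    dup <- vapply(key, function(k) !is.null(seen[[k]]), TRUE)
    if (any(dup)) dropped <- dropped + sum(dup)
    if (all(dup)) next
    for (k in key[!dup]) seen[[k]] <- TRUE
    idx <- at + seq_len(sum(!dup))
    states[rownames(cols[[i]]), idx] <- cols[[i]][, !dup, drop = FALSE]
    positions[idx] <- p[!dup]
    at <- at + sum(!dup)
  }
  if (dropped)
    warning(dropped, " reference positions covered by overlapping MAF ",
            "blocks; first block wins")
  states <- states[, seq_len(at), drop = FALSE]
  positions <- positions[seq_len(at)]
  o <- order(positions)
  ref_alignment(states[, o, drop = FALSE], reference, positions[o], chrom)
}

#' Write a reference-projected alignment as MAF
#'
#' Contiguous stretches of reference positions become blocks; the reference
#' row is ungapped by construction.  Non-reference rows are written with
#' start 0 on the + strand (synthetic alignments carry no meaningful
#' coordinates for non-reference species).
#'
#' @param aln A [ref_alignment()].
#' @param path Output path.
#' @export
write_maf <- function(aln, path) {
  stopifnot(inherits(aln, "ref_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  if (!ncol(aln$states)) return(invisible(path))
  brk <- c(0L, which(diff(aln$positions) != 1L), ncol(aln$states))
  srcsize <- max(aln$positions) + 1L
  for (i in seq_len(length(brk) - 1L)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    writeLines("a score=0", con)
    for (sp in rownames(aln$states)) {
      seqtxt <- paste(decode_bases(aln$states[sp, idx]), collapse = "")
      n_nt <- sum(aln$states[sp, idx] >= 0)
      if (sp == aln$reference) {
        writeLines(sprintf("s %s.%s %d %d + %d %s", sp, aln$chrom,
                           aln$positions[idx[1]], length(idx), srcsize,
                           seqtxt), con)
      } else {
        writeLines(sprintf("s %s.%s 0 %d + %d %s", sp, "contig",
                           n_nt, max(n_nt, 1L), seqtxt), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read a per-position rates track
#'
#' The rates format is positional plain text: line i holds the neutral rate
#' and RS score of the i-th reference position of the processed interval, as
#' two tab-separated numbers with six decimals.  Positions with no score
#' (fewer than 3 ungapped species, or no alignment) emit
#' `"0.000000\t0.000000"`.
#'
#' @param track A scored track data frame (see [score_alignment()]).
#' @param path Output path.
#' @return `write_rates` returns the path invisibly; `read_rates` returns a
#'   scored track whose `scored` flag is `neutral_rate > 0`.
#' @export
write_rates <- function(track, path) {
  n <- ifelse(track$scored, track$neutral_rate, 0)
  rs <- ifelse(track$scored, track$rs, 0)
  writeLines(sprintf("%.6f\t%.6f", n, rs), path)
  invisible(path)
}

#' @rdname write_rates
#' @param chrom Chromosome name to attach to the track.
#' @param start0 0-based reference position of the first line.
#' @export
read_rates <- function(path, chrom = "chr1", start0 = 0L) {
  d <- read.table(path, sep = "\t", col.names = c("neutral_rate", "rs"),
                  colClasses = "numeric")
  scored_track(pos = start0 + seq_len(nrow(d)) - 1L,
               neutral_rate = d$neutral_rate,
               rescaling = NA_real_,
               rs = d$rs,
               scored = d$neutral_rate > 0,
               chrom = chrom)
}

# scored-track constructor: plain data.frame with a chrom attribute
scored_track <- function(pos, neutral_rate, rescaling, rs, scored,
                         chrom = "chr1") {
  df <- data.frame(pos = as.integer(pos), neutral_rate = neutral_rate,
                   rescaling = rescaling, rs = rs, scored = as.logical(scored))
  attr(df, "chrom") <- chrom
  df
}

#' Write / read constrained elements as BED6+1
#'
#' Columns: chrom, 0-based half-open start and end, name (`elem_<rank>`),
#' score (summed RS), strand (`.`), and the p-value in scientific notation.
#'
#' @param elements Data frame with columns `chrom`, `start`, `end`, `rank`,
#'   `score`, `pvalue`, sorted by `start`.
#' @param path Output path.
#' @export
write_elements <- function(elements, path) {
  if (nrow(elements) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  stopifnot(!is.unsorted(elements$start))
  writeLines(sprintf("%s\t%d\t%d\telem_%d\t%g\t.\t%.1e",
                     elements$chrom, elements$start, elements$end,
                     elements$rank, elements$score, elements$pvalue),
             path)
  invisible(path)
}

#' @rdname write_elements
#' @export
read_elements <- function(path) {
  if (!length(readLines(path, n = 1L, warn = FALSE)))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), rank = integer(), score = numeric(),
                      pvalue = numeric()))
  d <- read.table(path, sep = "\t",
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand", "pvalue"))
  data.frame(chrom = d$chrom, start = d$start, end = d$end,
             rank = as.integer(sub("^elem_", "", d$name)),
             score = d$score, pvalue = d$pvalue)
}

#' Split a scored track into regions at unscored boundaries
#'
#' Long runs of unscored positions carry no usable information and elements
#' never span them, so they are natural region boundaries.  For each multiple
#' of `target_size` the unscored run (of length at least `boundary_gap`)
#' whose midpoint lies nearest is chosen as the split point; if no such run
#' exists the split falls at the exact multiple.
#'
#' @param track A scored track data frame.
#' @param target_size Approximate region size in positions (default 2e6).
#' @param boundary_gap Minimum unscored run length eligible as a boundary.
#' @return Data frame with 1-based row-index columns `start`, `end`
#'   (half-open) tiling the track.
#' @export
chunk_regions <- function(track, target_size = 2e6, boundary_gap = 10L) {
  stopifnot(target_size > 0)
  n <- nrow(track)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  nb <- max(0L, floor((n - 1) / target_size))
  if (nb == 0L) return(data.frame(start = 1L, end = n + 1L))
  r <- rle(!track$scored)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  elig <- r$values & r$lengths >= boundary_gap
  mids <- (starts[elig] + ends[elig]) / 2
  bounds <- integer(0)
  prev <- 1L
  for (k in seq_len(nb)) {
    tgt <- k * target_size
    b <- NA_integer_
    if (length(mids)) {
      i <- which.min(abs(mids - tgt))
      cand <- as.integer(floor(mids[i]))
      if (cand > prev && cand <= n) b <- cand
    }
    if (is.na(b)) b <- as.integer(min(tgt, n))
    if (b > prev && b <= n) {
      bounds <- c(bounds, b)
      prev <- b
    }
  }
  cuts <- unique(c(1L, bounds + 1L, n + 1L))
  data.frame(start = head(cuts, -1L), end = cuts[-1L])
}
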