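# Piecewise-linear, invertible maps between genome and fusion-contig
# coordinates. Segments are stored in genome order with "plus orientation"
# contig offsets; strand flipping and the geneB placement offset are applied
# arithmetically, so the map stays invertible on every retained base and bases
# removed by intron shrinking map to no contig position.

new_coordinate_map <- function(segments, strand, length, gene_id, offset = 0L) {
  stopifnot(all(c("gstart", "gend", "cstart") %in% names(segments)))
  segments <- segments[order(segments$gstart), , drop = FALSE]
  rownames(segments) <- NULL
  structure(
    list(segments = segments, strand = strand, length = as.integer(length),
         gene_id = gene_id, offset = as.integer(offset)),
    class = "CoordinateMap"
  )
}

#' Map genome positions to fusion-contig positions
#'
#' @param map A `CoordinateMap` (one gene's piece of a fusion contig).
#' @param gpos Integer vector of 0-based genome positions.
#' @return Integer vector of 0-based contig positions; `NA` for bases removed
#'   by intron shrinking or outside the gene span.
#' @export
map_genome_to_contig <- function(map, gpos) {
  seg <- map$segments
  idx <- findInterval(gpos, seg$gstart)
  out <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1 & idx <= nrow(seg)
  ok[ok] <- gpos[ok] < seg$gend[idx[ok]]
  local <- seg$cstart[idx[ok]] + (gpos[ok] - seg$gstart[idx[ok]])
  if (map$strand == "-") local <- map$length - 1L - local
  out[ok] <- as.integer(local + map$offset)
  out
}

#' Map fusion-contig positions back to genome positions
#'
#' Inverse of [map_genome_to_contig()] on retained bases.
#'
#' @param map A `CoordinateMap`.
#' @param cpos Integer vector of 0-based contig positions.
#' @return Integer vector of 0-based genome positions (`NA` outside this
#'   gene's contig segment).
#' @export
map_contig_to_genome <- function(map, cpos) {
  local <- cpos - map$offset
  out <- rep(NA_integer_, length(cpos))
  inside <- local >= 0L & local < map$length
  loc <- local[inside]
  if (map$strand == "-") loc <- map$length - 1L - loc
  seg <- map$segments
  cend <- seg$cstart + (seg$gend - seg$gstart)
  idx <- findInterval(loc, seg$cstart)
  ok <- idx >= 1 & loc < cend[idx]
  g <- rep(NA_integer_, length(loc))
  g[ok] <- as.integer(seg$gstart[idx[ok]] + (loc[ok] - seg$cstart[idx[ok]]))
  out[inside] <- g
  out
}

# Map a genome interval [gs, ge) that is fully retained (e.g. an exon) to the
# contig; returns c(cstart, cend) 0-based half-open in contig orientation.
map_interval_to_contig <- function(map, gs, ge) {
  a <- map_genome_to_contig(map, gs)
  b <- map_genome_to_contig(map, ge - 1L)
  if (is.na(a) || is.na(b)) stop("interval not fully retained on contig")
  c(min(a, b), max(a, b) + 1L)
}

#' @export
print.CoordinateMap <- function(x, ...) {
  cat(sprintf("CoordinateMap %s strand %s, %d segments, %d retained bases, offset %d\n",
              x$gene_id, x$strand, nrow(x$segments), x$length, x$offset))
  invisible(x)
}
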