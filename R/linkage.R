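#' Link genes to markers by physical windows
#'
#' A gene copy is physically linked to a marker when its [start, end] span
#' intersects the window of \code{window} bp up- and downstream of the
#' marker position on the same chromosome (\code{anchor = "overlap"}); with
#' \code{anchor = "start"} only the gene start coordinate is tested.
#' Interval intersection is computed with \pkg{GenomicRanges}. Markers with
#' zero linked genes are reported alongside the links.
#'
#' @param marker_ids markers to scan (must be in \code{marker_map}).
#' @param marker_map data.frame with marker_id, chromosome, position.
#' @param genes data.frame with gene_id, copy_index, chromosome, start, end
#'   (1-based inclusive).
#' @param window half-window in bp (default 5000).
#' @param anchor "overlap" (default) or "start".
#' @return list with \code{links} (marker_id, gene_id, copy_index,
#'   chromosome, gene_start, gene_end, distance) and \code{unlinked_markers}.
#' @export
link_genes <- function(marker_ids, marker_map, genes, window = 5000L,
                       anchor = c("overlap", "start")) {
  anchor <- match.arg(anchor)
  mm <- marker_map[match(marker_ids, marker_map$marker_id), , drop = FALSE]
  if (anyNA(mm$position)) stop("marker id(s) absent from map")
  win <- GenomicRanges::GRanges(
    mm$chromosome,
    IRanges::IRanges(pmax(1L, mm$position - window), mm$position + window))
  gend <- if (anchor == "start") genes$start else genes$end
  gr <- GenomicRanges::GRanges(genes$chromosome,
                               IRanges::IRanges(genes$start, gend))
  hits <- GenomicRanges::findOverlaps(win, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pos <- mm$position[qi]
  dist <- pmax(0L, pmax(genes$start[si] - pos, pos - genes$end[si]))
  links <- data.frame(marker_id = mm$marker_id[qi],
                      gene_id = genes$gene_id[si],
                      copy_index = genes$copy_index[si],
                      chromosome = genes$chromosome[si],
                      gene_start = genes$start[si],
                      gene_end = genes$end[si],
                      distance = as.integer(dist),
                      stringsAsFactors = FALSE)
  links <- links[order(links$chromosome, links$gene_start, links$marker_id), ]
  rownames(links) <- NULL
  list(links = links,
       unlinked_markers = setdiff(marker_ids, unique(links$marker_id)))
}

#' Genes with multiple linked genomic copies
#'
#' Genes whose distinct copies are linked to at least two distinct marker
#' regions, with copy counts and all marker associations.
#'
#' @param links the \code{links} data.frame from \code{\link{link_genes}}.
#' @return data.frame with gene_id, n_copies, n_markers, markers
#'   (comma-separated).
#' @export
multicopy_genes <- function(links) {
  if (!nrow(links))
    return(data.frame(gene_id = character(0), n_copies = integer(0),
                      n_markers = integer(0), markers = character(0)))
  by_gene <- split(links, links$gene_id)
  rows <- lapply(by_gene, function(d) {
    data.frame(gene_id = d$gene_id[1],
               n_copies = length(unique(d$copy_index)),
               n_markers = length(unique(d$marker_id)),
               markers = paste(sort(unique(d$marker_id)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_copies >= 2L & out$n_markers >= 2L, , drop = FALSE]
  out <- out[order(-out$n_copies, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# Gini importance bins used on the physical map
gini_bin <- function(importance) {
  cut(importance, breaks = c(-Inf, 0.2, 0.4, Inf),
      labels = c("<0.2", "0.2-0.4", ">0.4"), right = FALSE)
}

#' Plot-ready physical map table
#'
#' One row per feature: major markers, remaining intersection (FI-2)
#' markers, linked genes and duplicated genes, with trait/Gini/season
#' annotation where available, sorted by (chromosome, position).
#'
#' @param links links from \code{\link{link_genes}}.
#' @param major data.frame of major markers (marker_id, trait, importance,
#'   season).
#' @param fi2_markers character vector of all intersection markers.
#' @param marker_map marker map.
#' @return data.frame with chromosome, position, feature_type, label,
#'   gini_bin, season.
#' @export
physical_map_export <- function(links, major, fi2_markers, marker_map) {
  pos_of <- function(ids) marker_map$position[match(ids, marker_map$marker_id)]
  chr_of <- function(ids) marker_map$chromosome[match(ids, marker_map$marker_id)]
  major_rows <- data.frame(chromosome = chr_of(major$marker_id),
                           position = pos_of(major$marker_id),
                           feature_type = "major_marker",
                           label = paste0(major$marker_id, ":", major$trait),
                           gini_bin = as.character(gini_bin(major$importance)),
                           season = major$season, stringsAsFactors = FALSE)
  minor <- setdiff(fi2_markers, major$marker_id)
  minor_rows <- data.frame(chromosome = chr_of(minor), position = pos_of(minor),
                           feature_type = "fi2_marker", label = minor,
                           gini_bin = NA_character_, season = NA_character_,
                           stringsAsFactors = FALSE)
  dup_ids <- multicopy_genes(links)$gene_id
  gene_rows <- if (nrow(links)) {
    u <- unique(links[c("gene_id", "copy_index", "chromosome", "gene_start")])
    data.frame(chromosome = u$chromosome, position = u$gene_start,
               feature_type = ifelse(u$gene_id %in% dup_ids,
                                     "duplicated_gene", "gene"),
               label = paste0(u$gene_id, "_", u$copy_index),
               gini_bin = NA_character_, season = NA_character_,
               stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(major_rows, minor_rows, gene_rows)
  out <- out[order(out$chromosome, out$position), ]
  rownames(out) <- NULL
  out
}
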