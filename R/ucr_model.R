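#' @title UCR region and probe-tiling data model
#' @name ucr_model
#' @description
#' Ultraconserved regions (UCRs) are genomic segments of at least 200 bp with
#' perfect human/mouse/rat conservation. Each region can give rise to two
#' transcripts (T-UCRs), one per genomic strand, so the tiling design places
#' identical probe coordinates in two strand containers ("plus" and "minus").
#' Tiling covers the region core plus 2500 bases upstream and 500 bases
#' downstream, so that host-gene exons falling in the window can be measured
#' alongside the T-UCR itself.
#'
#' Coordinates are 0-based half-open throughout (BED convention).
NULL

REGION_CLASSES <- c("intergenic", "intronic", "exonic", "partly_exonic",
                    "unclassified")
INTRAGENIC_CLASSES <- c("intronic", "exonic", "partly_exonic")

REGION_COLS <- c("chrom", "start", "end", "id", "region_class",
                 "host_gene", "host_strand", "orientation")

#' Read UCR region annotations
#'
#' Reads an 8-column tab-separated region table (chrom, start, end, id,
#' region_class, host_gene, host_strand, orientation). Missing host fields may
#' be given as `0`, `.`, `NA` or empty. A header line is optional.
#'
#' Rows with `end <= start` and duplicated ids are rejected with an error that
#' names the offender. Regions shorter than 200 bp (the defining UCR minimum)
#' are kept but flagged in the `short` column with a warning, so toy-scale
#' fixtures remain usable.
#'
#' @param path path to the TSV/BED-style file.
#' @return a `data.frame` with one row per region and columns
#'   chrom, start, end, id, region_class, host_gene, host_strand,
#'   orientation, short.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("^chrom\\b", first)
  df <- tryCatch(
    if (has_header) {
      utils::read.delim(path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      utils::read.delim(path, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE, col.names = REGION_COLS)
    },
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("read_regions(): no region rows in ", path)
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(REGION_COLS)), REGION_COLS))
    df$start <- df$end <- numeric(0)
    df$short <- logical(0)
    return(df)
  }
  names(df) <- REGION_COLS[seq_len(ncol(df))]
  validate_regions(df)
}

validate_regions <- function(df) {
  if (!all(REGION_COLS %in% names(df)))
    stop("region table must have columns: ", paste(REGION_COLS, collapse = ", "),
         call. = FALSE)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric region coordinates", call. = FALSE)
  bad <- df$end <= df$start
  if (any(bad))
    stop("degenerate interval (end <= start) for region(s): ",
         paste(df$id[bad], collapse = ", "), call. = FALSE)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate region id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (col in c("host_gene", "host_strand", "orientation"))
    df[[col]] <- ifelse(df[[col]] %in% c("0", ".", "", "NA", NA),
                        NA_character_, as.character(df[[col]]))
  unknown <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(unknown))
    stop("unknown region_class value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  intragenic <- df$region_class %in% INTRAGENIC_CLASSES
  if (any(intragenic & (is.na(df$host_gene) | is.na(df$host_strand))))
    stop("intragenic region(s) missing host_gene/host_strand: ",
         paste(df$id[intragenic & (is.na(df$host_gene) | is.na(df$host_strand))],
               collapse = ", "), call. = FALSE)
  df$host_gene[df$region_class == "intergenic"] <- NA_character_
  df$short <- (df$end - df$start) < 200
  if (any(df$short))
    warning("region(s) shorter than 200 bp flagged: ",
            paste(df$id[df$short], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write UCR region annotations
#'
#' @param regions a region `data.frame` as returned by [read_regions()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  out <- regions[, REGION_COLS]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  for (col in c("host_gene", "host_strand", "orientation"))
    out[[col]][is.na(out[[col]])] <- "0"
  write_tsv_file(out, path)
}

#' Read host-gene exon annotations
#'
#' Accepts a 5-column TSV (gene, chrom, start, end, strand; 0-based
#' half-open). Exons of a gene are merged if they overlap, so downstream
#' overlap counting never double-counts a base.
#'
#' @param path path to the exon TSV.
#' @return `data.frame` with columns gene, chrom, start, end, strand.
#' @export
read_exons <- function(path) {
  df <- read_tsv_file(path)
  validate_exons(df)
}

validate_exons <- function(df) {
  need <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("exon table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("exon strand must be + or -", call. = FALSE)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$end <= df$start)) stop("degenerate exon interval", call. = FALSE)
  # merge overlapping exons within a gene
  out <- do.call(rbind, lapply(split(df, df$gene), function(g) {
    g <- g[order(g$start), ]
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    data.frame(gene = g$gene[1], chrom = g$chrom[1],
               start = IRanges::start(ir) - 1, end = IRanges::end(ir),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tiled window of a region
#'
#' Upstream/downstream flanks are oriented by the host-gene strand for
#' intragenic regions and by the + genomic strand otherwise, so "2500 bp
#' upstream" always means upstream in the transcriptional sense of the host.
#'
#' @param region one-row region data.frame (or list) with start/end,
#'   region_class, host_strand.
#' @param upstream,downstream flank sizes in bases.
#' @return numeric vector `c(window_start, window_end)`.
#' @export
tiled_window <- function(region, upstream = 2500, downstream = 500) {
  minus <- !is.na(region$host_strand) && region$host_strand == "-" &&
    region$region_class %in% INTRAGENIC_CLASSES
  if (minus) c(region$start - downstream, region$end + upstream)
  else c(region$start - upstream, region$end + downstream)
}

#' Oligo melting temperature from GC count
#'
#' Closed-form salt-adjusted GC formula, `Tm = 64.9 + 41 (gc - 16.4) / len`.
#' Any monotone Tm model supports length selection for Tm matching; this one
#' is testable in closed form.
#'
#' @param gc_count number of G/C bases in the oligo.
#' @param len oligo length in bases.
#' @export
probe_tm <- function(gc_count, len) 64.9 + 41 * (gc_count - 16.4) / len

#' Tile a region with strand-paired probes
#'
#' Probes start every `step` bases across the tiled window, plus one
#' end-anchored probe so the final window bases are always covered. At every
#' start, the probe length in 50..72 is chosen to bring the GC-model Tm
#' closest to `tm_target` (ties go to the shorter oligo); probes that would
#' overhang the window are shifted left so every probe interval stays inside
#' the window. Identical coordinates are emitted for the plus and minus
#' strand containers.
#'
#' @param region one-row region data.frame.
#' @param step tiling step in bases (>= 1).
#' @param tm_target target melting temperature in degrees C.
#' @param gc either a single GC fraction applied uniformly, or a logical/0-1
#'   vector marking G/C bases along the window (length = window length).
#' @param upstream,downstream flank sizes in bases.
#' @return probe `data.frame`: probe_id, region, container, start, length,
#'   zone (unset, see [assign_zones()]), tm, window_start, window_end.
#' @export
tile_region <- function(region, step = 45, tm_target = 76, gc = 0.5,
                        upstream = 2500, downstream = 500) {
  stopifnot(step >= 1)
  win <- tiled_window(region, upstream, downstream)
  w <- win[2] - win[1]
  lens <- 50:72
  if (w < 50) {
    warning("window of region ", region$id, " shorter than 50 bases; ",
            "emitting a single full-window probe")
    offs <- 0
    lens <- as.integer(w)
  } else {
    offs <- seq(0, w, by = step)
    # final offset anchors an end probe so the last window bases are covered
    if (offs[length(offs)] < w) offs <- c(offs, w)
  }
  len_mat <- matrix(lens, nrow = length(offs), ncol = length(lens),
                    byrow = TRUE)
  if (length(gc) == 1L) {
    gc_count <- len_mat * gc
  } else {
    if (length(gc) != w)
      stop("gc vector must have one entry per window base (", w, ")",
           call. = FALSE)
    cs <- c(0, cumsum(as.numeric(gc)))
    # candidate start for offset o and length L is min(o, w - L)
    starts <- outer(offs, lens, function(o, L) pmin(o, w - L))
    gc_count <- matrix(cs[starts + len_mat + 1] - cs[starts + 1],
                       nrow = length(offs))
  }
  tm <- 64.9 + 41 * (gc_count - 16.4) / len_mat
  pick <- apply(abs(tm - tm_target), 1, which.min)  # ties -> shorter (first)
  len <- lens[pick]
  tm_sel <- tm[cbind(seq_along(pick), pick)]
  start <- win[1] + pmin(offs, w - len)
  one <- function(container) data.frame(
    probe_id = sprintf("%s_%s_p%03d", region$id,
                       ifelse(container == "plus", "p", "m"),
                       seq_along(offs)),
    region = region$id, container = container,
    start = start, length = len, zone = NA_character_, tm = tm_sel,
    window_start = win[1], window_end = win[2],
    stringsAsFactors = FALSE)
  out <- rbind(one("plus"), one("minus"))
  rownames(out) <- NULL
  out
}

#' Assign probes to window zones
#'
#' A probe belongs to the `core` zone iff its midpoint lies inside the region
#' interval `[start, end)`; otherwise it is an upstream or downstream flank
#' probe, with the flank direction taken relative to the host-gene strand
#' (+ genomic strand for intergenic regions). Core probes feed the T-UCR
#' summary; flank probes are retained for host-exon expression only.
#'
#' @param probes probe data.frame from [tile_region()].
#' @param region the matching one-row region data.frame.
#' @return probes with the `zone` column filled.
#' @export
assign_zones <- function(probes, region) {
  stopifnot(all(probes$region == region$id))
  out_of_window <- probes$start < probes$window_start |
    probes$start + probes$length > probes$window_end
  if (any(out_of_window))
    stop("probe(s) outside tiled window: ",
         paste(probes$probe_id[out_of_window], collapse = ", "), call. = FALSE)
  mid <- probes$start + probes$length / 2
  minus_host <- !is.na(region$host_strand) && region$host_strand == "-" &&
    region$region_class %in% INTRAGENIC_CLASSES
  zone <- ifelse(mid >= region$start & mid < region$end, "core",
                 ifelse(mid < region$start,
                        if (minus_host) "downstream_flank" else "upstream_flank",
                        if (minus_host) "upstream_flank" else "downstream_flank"))
  probes$zone <- zone
  probes
}

#' Tile many regions and assign zones
#'
#' @inheritParams tile_region
#' @param regions region data.frame.
#' @param gc_list optional named list of per-region GC vectors.
#' @export
tile_regions <- function(regions, step = 45, tm_target = 76, gc = 0.5,
                         gc_list = NULL, upstream = 2500, downstream = 500) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- if (!is.null(gc_list)) gc_list[[r$id]] else gc
    assign_zones(tile_region(r, step, tm_target, g, upstream, downstream), r)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map probes to host-gene exons
#'
#' A probe is mapped to a gene iff its interval overlaps at least one exon
#' base of that gene and the probe sits in the strand container matching the
#' gene's strand (host expression is read from the gene's own strand;
#' antisense-container probes over an exon are never counted).
#'
#' @param probes probe data.frame (zones assigned).
#' @param exons exon data.frame from [read_exons()].
#' @param regions region data.frame (supplies each probe's host gene).
#' @return `data.frame` with columns probe_id, gene.
#' @export
exon_probe_map <- function(probes, exons, regions) {
  host <- stats::setNames(regions$host_gene, regions$id)
  strand_of <- stats::setNames(exons$strand, exons$gene)
  probes$host_gene <- host[probes$region]
  cand <- probes[!is.na(probes$host_gene), , drop = FALSE]
  if (nrow(cand) == 0L || nrow(exons) == 0L)
    return(data.frame(probe_id = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  missing_genes <- setdiff(unique(cand$host_gene), exons$gene)
  if (length(missing_genes))
    message("exon_probe_map(): no exon annotation for gene(s): ",
            paste(missing_genes, collapse = ", "))
  # container must match the host-gene strand
  cont_strand <- c(plus = "+", minus = "-")[cand$container]
  cand <- cand[!is.na(strand_of[cand$host_gene]) &
                 cont_strand == strand_of[cand$host_gene], , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(probe_id = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  hits <- lapply(split(cand, cand$host_gene), function(p) {
    ex <- exons[exons$gene == p$host_gene[1], , drop = FALSE]
    if (nrow(ex) == 0L) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(p$start + 1, p$start + p$length),
      IRanges::IRanges(ex$start + 1, ex$end))
    if (length(ov) == 0L) return(NULL)
    data.frame(probe_id = p$probe_id[unique(S4Vectors::queryHits(ov))],
               gene = p$host_gene[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(probe_id = character(0), gene = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Transcript bookkeeping for a region table
#'
#' Every region yields two strand-container transcripts. Orientation relative
#' to the host gene is derived from the container and the host strand;
#' intergenic and unclassified regions have no host orientation, and their
#' plus container is taken as the sense container for reorientation.
#'
#' @param regions region data.frame.
#' @return `data.frame` with columns transcript_id, region, container,
#'   region_class, host_gene, host_strand, orientation.
#' @export
transcript_table <- function(regions) {
  one <- function(container) {
    ori <- ifelse(regions$region_class %in% INTRAGENIC_CLASSES,
                  ifelse(c(plus = "+", minus = "-")[container] ==
                           regions$host_strand, "sense", "anti-sense"),
                  NA_character_)
    data.frame(transcript_id = paste0(regions$id, "_", container),
               region = regions$id, container = container,
               region_class = regions$region_class,
               host_gene = regions$host_gene,
               host_strand = regions$host_strand,
               orientation = ori, stringsAsFactors = FALSE)
  }
  out <- rbind(one("plus"), one("minus"))
  out <- out[order(match(out$region, regions$id), out$container), ]
  rownames(out) <- NULL
  out
}
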