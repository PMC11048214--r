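#' Circular rCRS region atlas
#'
#' The atlas maps every position of the 16,569-bp circular human mitochondrial
#' reference (rCRS, NC_012920.1) to a top-level compartment (control region,
#' coding locus, or non-coding nucleotide) and to nested control-region
#' annotations: hypervariable segments (HV1-3), replication/transcription
#' functional domains (ETAS, CSB, LSP, central domain), single-strand DNA
#' secondary-structure elements (A-M), and homopolymeric tracts that are
#' artifact-prone in short-read calling.
#'
#' Coordinates are 1-based inclusive. Intervals with `start > end` wrap through
#' the origin (16,569 -> 1); the bundled control region spans 16024-576 and
#' therefore contains 1,122 positions.
#'
#' @param path Path to an atlas interval file. `NULL` (default) loads the
#'   bundled rCRS atlas.
#' @param dialect Coordinate dialect of `path`: `"tsv"` (native, 1-based
#'   inclusive, columns `label`, `category`, `start`, `end`) or `"bed"`
#'   (0-based half-open, columns chrom/start/end/label/category; converted on
#'   load).
#' @param genome_length Length of the circular genome (16,569 for rCRS).
#' @return An object of class `mito_atlas`: a list with `genome_length`,
#'   `intervals` (data frame), and a precomputed per-position top-level index.
#' @examples
#' atlas <- load_atlas()
#' assign_region(atlas, c(7410, 16304, 300))
#' @export
load_atlas <- function(path = NULL, dialect = c("tsv", "bed"),
                       genome_length = 16569L) {
  dialect <- match.arg(dialect)
  if (is.null(path)) {
    path <- system.file("extdata", "rcrs_atlas.tsv", package = "mitovar")
  }
  if (!file.exists(path)) stop("atlas file not found: ", path)
  if (dialect == "tsv") {
    iv <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("label", "category", "start", "end")
    if (!all(need %in% names(iv))) {
      stop("atlas TSV must have columns: ", paste(need, collapse = ", "))
    }
  } else {
    bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 5) stop("atlas BED needs chrom,start,end,label,category")
    # BED is 0-based half-open; convert to 1-based inclusive
    iv <- data.frame(label = bed[[4]], category = bed[[5]],
                     start = as.integer(bed[[2]]) + 1L,
                     end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  }
  build_atlas(iv, genome_length)
}

# Validate intervals and precompute position indices.
build_atlas <- function(intervals, genome_length = 16569L) {
  iv <- intervals
  if (nrow(iv) == 0L) stop("atlas contains no intervals")
  iv$start <- as.integer(iv$start)
  iv$end <- as.integer(iv$end)
  ok_cat <- c("gene", "rRNA", "tRNA", "CR", "HV", "functional_domain",
              "structure_element", "homopolymer", "non_coding")
  bad <- setdiff(unique(iv$category), ok_cat)
  if (length(bad)) stop("unknown atlas categories: ", paste(bad, collapse = ", "))
  out <- iv$start < 1L | iv$start > genome_length |
    iv$end < 1L | iv$end > genome_length
  if (any(out)) {
    stop("atlas coordinates out of range 1..", genome_length, ": ",
         paste(iv$label[out], collapse = ", "))
  }
  dup <- duplicated(iv[, c("category", "label")])
  if (any(dup)) {
    stop("duplicated atlas labels within a category: ",
         paste(iv$label[dup], collapse = ", "))
  }

  # top-level partition: CR + gene/rRNA/tRNA + non_coding
  top <- iv[iv$category %in% c("CR", "gene", "rRNA", "tRNA", "non_coding"), ]
  topmap <- integer(genome_length)        # 0 = unassigned
  for (i in seq_len(nrow(top))) {
    pos <- interval_positions(top$start[i], top$end[i], genome_length)
    if (any(topmap[pos] != 0L)) {
      clash <- top$label[topmap[pos][topmap[pos] != 0L][1]]
      stop("overlapping top-level atlas intervals: ", top$label[i],
           " overlaps ", clash)
    }
    topmap[pos] <- i
  }
  if (any(topmap == 0L)) {
    stop("atlas top-level intervals do not cover the genome (",
         sum(topmap == 0L), " positions unassigned)")
  }

  # CR-nested annotations must sit inside the CR span
  cr_mask <- top$category[topmap] == "CR"
  for (cat in c("HV", "functional_domain")) {
    sub <- iv[iv$category == cat, ]
    for (i in seq_len(nrow(sub))) {
      pos <- interval_positions(sub$start[i], sub$end[i], genome_length)
      if (!all(cr_mask[pos])) {
        stop(cat, " interval ", sub$label[i], " extends outside the CR span")
      }
    }
  }

  structure(list(genome_length = genome_length, intervals = iv,
                 top = top, topmap = topmap),
            class = "mito_atlas")
}

# Expand a possibly wrap-spanning 1-based inclusive interval into positions.
interval_positions <- function(start, end, genome_length) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, genome_length),
                                               seq.int(1L, end))
}

# TRUE for positions inside interval (start, end), wrap-aware, vectorised
# over positions.
in_interval <- function(positions, start, end, genome_length) {
  if (start <= end) positions >= start & positions <= end
  else positions >= start | positions <= end
}

#' @export
print.mito_atlas <- function(x, ...) {
  cat("<mito_atlas> circular genome of", x$genome_length, "bp;",
      nrow(x$intervals), "intervals in",
      length(unique(x$intervals$category)), "categories\n")
  invisible(x)
}

check_positions <- function(atlas, positions) {
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L) ||
      any(positions > atlas$genome_length)) {
    stop("positions must lie in 1..", atlas$genome_length)
  }
  positions
}

#' Assign rCRS positions to atlas regions
#'
#' Deterministically maps each position to its top-level compartment and, for
#' control-region positions, its hypervariable segment and functional domain.
#' Secondary-structure element membership and homopolymer status are reported
#' for all positions.
#'
#' @param atlas A `mito_atlas` from [load_atlas()].
#' @param positions Integer vector of rCRS coordinates (1-based).
#' @return A data frame with one row per position: `position`, `top_level`
#'   (`"CR"`, `"coding"`, `"non_coding"`), `gene` (locus label or `NA`), `hv`
#'   (`"HV1"`/`"HV2"`/`"HV3"`/`"no-HV"` inside the CR, `"n/a"` elsewhere),
#'   `functional_domain` (`"ETAS"`, `"CSB"`, `"LSP"`, `"CENTRAL_DOMAIN"`,
#'   `"none"` inside the CR, `"n/a"` elsewhere), `structure_elements`
#'   (comma-separated element labels or `""`), and `homopolymer` (logical).
#' @export
assign_region <- function(atlas, positions) {
  stopifnot(inherits(atlas, "mito_atlas"))
  positions <- check_positions(atlas, positions)
  idx <- atlas$topmap[positions]
  cat0 <- atlas$top$category[idx]
  top_level <- ifelse(cat0 == "CR", "CR",
                      ifelse(cat0 == "non_coding", "non_coding", "coding"))
  gene <- ifelse(top_level == "coding", atlas$top$label[idx], NA_character_)

  lookup_label <- function(category, default_in, default_out, collapse = FALSE) {
    sub <- atlas$intervals[atlas$intervals$category == category, ]
    res <- rep(default_out, length(positions))
    in_cr <- top_level == "CR"
    res[in_cr] <- default_in
    if (collapse) res <- rep("", length(positions))
    for (i in seq_len(nrow(sub))) {
      hit <- in_interval(positions, sub$start[i], sub$end[i],
                         atlas$genome_length)
      if (collapse) {
        res[hit] <- ifelse(res[hit] == "", sub$label[i],
                           paste(res[hit], sub$label[i], sep = ","))
      } else {
        res[hit] <- sub$label[i]
      }
    }
    res
  }

  hv <- lookup_label("HV", "no-HV", "n/a")
  dom_label <- lookup_label("functional_domain", "none", "n/a")
  # group ETAS1/ETAS2 -> ETAS, CSB1-3 -> CSB
  dom <- dom_label
  dom[grepl("^ETAS", dom_label)] <- "ETAS"
  dom[grepl("^CSB", dom_label)] <- "CSB"
  se <- lookup_label("structure_element", "", "", collapse = TRUE)
  hp <- is_homopolymer(atlas, positions)

  data.frame(position = positions, top_level = top_level, gene = gene,
             hv = hv, functional_domain = dom, structure_elements = se,
             homopolymer = hp, stringsAsFactors = FALSE)
}

#' Homopolymeric-tract membership
#'
#' Short-read mtDNA calls inside homopolymeric tracts are artifact-prone and
#' are disregarded by the retention filter. The bundled tract list is
#' 66-71, 300-316, 513-525, 5892, 3106-3107, 12418-12425 and 16182-16194.
#'
#' @inheritParams assign_region
#' @return Logical vector, `TRUE` where the position lies in a listed tract.
#' @export
is_homopolymer <- function(atlas, positions) {
  stopifnot(inherits(atlas, "mito_atlas"))
  positions <- check_positions(atlas, positions)
  hp <- atlas$intervals[atlas$intervals$category == "homopolymer", ]
  res <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(hp))) {
    res <- res | in_interval(positions, hp$start[i], hp$end[i],
                             atlas$genome_length)
  }
  res
}

#' Positions belonging to an atlas category or label
#'
#' Convenience accessor used by the cohort simulator (e.g. all control-region
#' positions, or all homopolymer positions).
#'
#' @inheritParams assign_region
#' @param category Atlas category to expand.
#' @param label Optional label filter within the category.
#' @return Sorted integer vector of unique positions.
#' @export
atlas_positions <- function(atlas, category, label = NULL) {
  stopifnot(inherits(atlas, "mito_atlas"))
  sub <- atlas$intervals[atlas$intervals$category == category, ]
  if (!is.null(label)) sub <- sub[sub$label %in% label, ]
  if (nrow(sub) == 0L) return(integer(0))
  pos <- unlist(lapply(seq_len(nrow(sub)), function(i) {
    interval_positions(sub$start[i], sub$end[i], atlas$genome_length)
  }))
  sort(unique(pos))
}
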