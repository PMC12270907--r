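#' @include simulate-reads.R
NULL

#' Demultiplex plate-based reads by exact barcode match
#'
#' Reads conform to the layout \code{(3 nt UMI)(8 nt barcode)(gDNA)}. A read
#' is assigned to a cell iff positions 4-11 exactly match a whitelisted
#' barcode (zero mismatches); the UMI is positions 1-3. Barcode and UMI are
#' trimmed off; the UMI is retained in the record metadata.
#'
#' @param reads data.frame/data.table with columns \code{name} and
#'   \code{sequence}.
#' @param barcodeTable data.frame mapping \code{barcode} (8 nt, all distinct)
#'   to \code{cell}.
#' @return data.table with columns \code{name}, \code{cell} (NA when
#'   unassigned), \code{umi}, \code{insert}.
#' @export
demultiplex <- function(reads, barcodeTable) {
  if (anyDuplicated(barcodeTable$barcode))
    stop("barcode table contains duplicate barcodes")
  if (any(nchar(barcodeTable$barcode) != 8L))
    stop("barcodes must be 8 nt")
  reads <- data.table::as.data.table(reads)
  if (!nrow(reads)) {
    return(data.table::data.table(name = character(), cell = character(),
                                  umi = character(), insert = character()))
  }
  umi <- substring(reads$sequence, 1L, 3L)
  bc <- substring(reads$sequence, 4L, 11L)
  idx <- match(bc, barcodeTable$barcode)
  data.table::data.table(
    name = reads$name,
    cell = barcodeTable$cell[idx],
    umi = umi,
    insert = substring(reads$sequence, 12L)
  )
}

# Cache of forward chromosome strings plus their reverse complements.
.genomeSearchStrings <- function(genome) {
  fwd <- chromStrings(genome)
  list(fwd = fwd)
}

.findAllFixed <- function(pattern, subject) {
  h <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  h[h > 0]
}

#' Exact-match alignment of an insert against a toy genome
#'
#' Searches the insert (optionally with \code{GA} prepended, reconstructing
#' the digested DamID fragment) as an exact substring on both strands of
#' every chromosome. A unique hit receives a high mapping quality (42); more
#' than one hit receives a mapping quality of 3 (below the conventional
#' MAPQ >= 10 filter); no hit leaves the read unaligned.
#'
#' @param inserts Character vector of insert sequences.
#' @param genome A [GenomeModel-class].
#' @param prependGA Prepend \code{GA} before searching.
#' @param minLen Minimum insert length (before prepending); shorter inserts
#'   are reported with status \code{too_short}.
#' @return data.table with one row per insert: \code{chrom}, \code{pos}
#'   (1-based leftmost position of the match), \code{strand}, \code{mapq},
#'   \code{nHits}, \code{status} (\code{unique}, \code{multi},
#'   \code{unaligned}, \code{too_short}).
#' @export
toyAlign <- function(inserts, genome, prependGA = FALSE, minLen = 20L) {
  ss <- chromStrings(genome)
  chrs <- names(ss)
  n <- length(inserts)
  out <- data.table::data.table(
    chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
    strand = rep(NA_character_, n), mapq = rep(NA_integer_, n),
    nHits = rep(0L, n), status = rep("unaligned", n)
  )
  for (i in seq_len(n)) {
    ins <- inserts[i]
    if (is.na(ins) || nchar(ins) < minLen) {
      data.table::set(out, i, "status", "too_short")
      next
    }
    qry <- if (prependGA) paste0("GA", ins) else ins
    qrc <- .revcomp(qry)
    hits <- list()
    for (ch in chrs) {
      for (p in .findAllFixed(qry, ss[[ch]]))
        hits[[length(hits) + 1L]] <- list(chrom = ch, pos = p, strand = "+")
      for (p in .findAllFixed(qrc, ss[[ch]]))
        hits[[length(hits) + 1L]] <- list(chrom = ch, pos = p, strand = "-")
    }
    nh <- length(hits)
    data.table::set(out, i, "nHits", nh)
    if (nh == 0L) next
    h <- hits[[1L]]
    data.table::set(out, i, "chrom", h$chrom)
    data.table::set(out, i, "pos", as.integer(h$pos))
    data.table::set(out, i, "strand", h$strand)
    data.table::set(out, i, "mapq", if (nh == 1L) 42L else 3L)
    data.table::set(out, i, "status", if (nh == 1L) "unique" else "multi")
  }
  out
}

#' Classify demultiplexed reads as DamID or ChIC by sequence context
#'
#' Implements in silico modality separation. Each insert is first aligned
#' with a prepended \code{GA} dinucleotide (reconstructing the fragment
#' digested at the motif): a unique, perfect alignment whose GATC lands on a
#' recorded motif makes the read DamID, recorded at the motif start on the
#' event's strand. Residual reads are realigned as-is and called ChIC iff
#' they align uniquely, start with \code{A} or \code{T} (MNase cut
#' preference), and - for combined dual-modality libraries - do not start
#' with the excluded \code{TC} dinucleotide. Everything else (including
#' multi-mappers below the MAPQ threshold) is discarded.
#'
#' @param demuxed Output of [demultiplex()]; rows with \code{NA} cell are
#'   ignored.
#' @param genome A [GenomeModel-class].
#' @param combinedLibrary TRUE for dual-modality libraries (enables the TC
#'   exclusion); FALSE for ChIC-only libraries.
#' @param mapqMin Minimum mapping quality (default 10).
#' @param minLen Minimum insert length passed to [toyAlign()].
#' @return data.table of aligned events: \code{name}, \code{cell},
#'   \code{umi}, \code{chrom}, \code{pos} (motif start for DamID, cut site
#'   for ChIC), \code{strand}, \code{modality} (\code{damid}, \code{chic} or
#'   \code{discarded}), \code{allele} (\code{none}), \code{mapq}.
#' @export
classifyModality <- function(demuxed, genome, combinedLibrary = TRUE,
                             mapqMin = 10L, minLen = 20L) {
  dm <- data.table::as.data.table(demuxed)
  dm <- dm[!is.na(dm$cell)]
  n <- nrow(dm)
  res <- data.table::data.table(
    name = dm$name, cell = dm$cell, umi = dm$umi,
    chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
    strand = rep(NA_character_, n),
    modality = rep("discarded", n), allele = rep("none", n),
    mapq = rep(NA_integer_, n)
  )
  if (!n) return(res)
  ga <- toyAlign(dm$insert, genome, prependGA = TRUE, minLen = minLen)
  gpos <- gatcPositions(genome)
  insLen <- nchar(dm$insert)
  isDamid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (identical(ga$status[i], "unique") && ga$mapq[i] >= mapqMin) {
      L <- insLen[i] + 2L
      motif <- if (ga$strand[i] == "+") ga$pos[i] else ga$pos[i] + L - 4L
      if (motif %in% gpos[[ga$chrom[i]]]) {
        isDamid[i] <- TRUE
        data.table::set(res, i, "chrom", ga$chrom[i])
        data.table::set(res, i, "pos", motif)
        data.table::set(res, i, "strand", ga$strand[i])
        data.table::set(res, i, "modality", "damid")
        data.table::set(res, i, "mapq", ga$mapq[i])
      }
    }
  }
  first1 <- substring(dm$insert, 1L, 1L)
  first2 <- substring(dm$insert, 1L, 2L)
  chicCand <- which(!isDamid & first1 %in% c("A", "T") &
                    !(combinedLibrary & first2 == "TC"))
  if (length(chicCand)) {
    al <- toyAlign(dm$insert[chicCand], genome, prependGA = FALSE,
                   minLen = minLen)
    for (k in seq_along(chicCand)) {
      if (!identical(al$status[k], "unique") || al$mapq[k] < mapqMin) next
      i <- chicCand[k]
      cut <- if (al$strand[k] == "+") al$pos[k]
             else al$pos[k] + insLen[i] - 1L
      data.table::set(res, i, "chrom", al$chrom[k])
      data.table::set(res, i, "pos", cut)
      data.table::set(res, i, "strand", al$strand[k])
      data.table::set(res, i, "modality", "chic")
      data.table::set(res, i, "mapq", al$mapq[k])
    }
  }
  res
}

#' Assign a read to a parental allele from paired alignment records
#'
#' The allele whose alignment has the lower edit distance wins; on an edit
#' distance tie the higher alignment score wins; a tie on both is ambiguous.
#' A missing alignment on one allele lets the other win; both missing yields
#' \code{none}.
#'
#' @param nmA,nmB Edit distances (NM) against allele A / allele B; NA when
#'   the read did not align to that genotype.
#' @param asA,asB Alignment scores (AS); same length.
#' @return Character vector in \code{allele_a}, \code{allele_b},
#'   \code{ambiguous}, \code{none}.
#' @examples
#' assignAllele(0, 40, 2, 40)              # allele_a
#' assignAllele(1, 40, 1, 60)              # allele_b
#' assignAllele(1, 50, 1, 50)              # ambiguous
#' @export
assignAllele <- function(nmA, asA, nmB, asB) {
  n <- max(length(nmA), length(nmB))
  nmA <- rep_len(nmA, n); asA <- rep_len(asA, n)
  nmB <- rep_len(nmB, n); asB <- rep_len(asB, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is.na(nmA[i]) && is.na(nmB[i])) "none"
    else if (is.na(nmB[i])) "allele_a"
    else if (is.na(nmA[i])) "allele_b"
    else if (nmA[i] < nmB[i]) "allele_a"
    else if (nmB[i] < nmA[i]) "allele_b"
    else if (asA[i] > asB[i]) "allele_a"
    else if (asB[i] > asA[i]) "allele_b"
    else "ambiguous"
  }
  out
}

#' Collapse PCR duplicates into UMI-unique events
#'
#' Events are collapsed per cell and modality on (chrom, position, strand,
#' UMI): multiple reads with the same key count as one unique event. Under
#' haploid or allele-resolved counting a collapsed group contributes 1 to the
#' unique-event count; under diploid counting it contributes 2 (the event may
#' have occurred on either homologue).
#'
#' @param events data.frame with columns \code{cell}, \code{chrom},
#'   \code{pos}, \code{strand}, \code{umi}, \code{modality} and optionally
#'   \code{allele}; rows with modality \code{discarded} are dropped.
#' @param ploidy \code{"haploid_or_allelic"} or \code{"diploid"}.
#' @return An [EventTable-class] of UMI-unique events with per-event weight.
#' @export
dedupEvents <- function(events, ploidy = c("haploid_or_allelic", "diploid")) {
  ploidy <- match.arg(ploidy)
  ev <- data.table::as.data.table(events)
  if (!"allele" %in% colnames(ev)) ev$allele <- "none"
  ev <- ev[ev$modality %in% c("damid", "chic")]
  keyCols <- c("cell", "modality", "chrom", "pos", "strand", "umi")
  ev <- unique(ev, by = keyCols)
  ev <- ev[, c(keyCols[c(1, 3:6, 2)], "allele"), with = FALSE]
  ev$weight <- if (ploidy == "diploid") 2L else 1L
  data.table::setorderv(ev, c("cell", "modality", "chrom", "pos", "strand",
                              "umi"))
  methods::new("EventTable", events = ev, ploidy = ploidy)
}

.DAMID_CUTOFFS <- c(dam = 1000L, dam_scfv_h3k27me3 = 1000L, dam_lmnb1 = 5000L)

#' Per-cell quality filtering on UMI-unique read counts
#'
#' Applies construct-specific cutoffs on DamID UMI-unique events (1,000 for
#' Dam and Dam-scFv-H3K27me3; 5,000 for Dam-LMNB1) and a general ChIC cutoff
#' of 1,000. In allele-resolved mode each cell additionally needs at least
#' 200 UMI-unique events per parental allele for each modality. All
#' comparisons are inclusive (>= threshold).
#'
#' @param eventTable An [EventTable-class].
#' @param construct One of \code{dam}, \code{dam_scfv_h3k27me3},
#'   \code{dam_lmnb1}.
#' @param allelic Apply the per-allele requirement.
#' @param damidCutoff,chicCutoff,allelicCutoff Override the defaults.
#' @return data.table with per-cell counts, \code{pass} and \code{reason}.
#' @export
filterCells <- function(eventTable, construct = c("dam", "dam_scfv_h3k27me3",
                                                  "dam_lmnb1"),
                        allelic = FALSE, damidCutoff = NULL,
                        chicCutoff = 1000L, allelicCutoff = 200L) {
  construct <- match.arg(construct)
  if (is.null(damidCutoff)) damidCutoff <- .DAMID_CUTOFFS[[construct]]
  ev <- eventTable@events
  cells <- sort(unique(ev$cell))
  cnt <- uniqueCounts(eventTable)
  getN <- function(cl, mod) {
    v <- cnt$n[cnt$cell == cl & cnt$modality == mod]
    if (length(v)) v else 0
  }
  out <- data.table::data.table(cell = cells, nDamid = 0, nChic = 0,
                                pass = TRUE, reason = "")
  for (i in seq_along(cells)) {
    nd <- getN(cells[i], "damid"); nc <- getN(cells[i], "chic")
    reasons <- character(0)
    if (nd < damidCutoff) reasons <- c(reasons, "damid_below_cutoff")
    if (nc < chicCutoff) reasons <- c(reasons, "chic_below_cutoff")
    if (allelic) {
      sub <- ev[ev$cell == cells[i]]
      for (mod in c("damid", "chic")) for (al in c("allele_a", "allele_b")) {
        na <- sum(sub$weight[sub$modality == mod & sub$allele == al])
        if (na < allelicCutoff)
          reasons <- c(reasons, paste0(mod, "_", al, "_below_allelic_cutoff"))
      }
    }
    data.table::set(out, i, "nDamid", nd)
    data.table::set(out, i, "nChic", nc)
    data.table::set(out, i, "pass", length(reasons) == 0L)
    data.table::set(out, i, "reason", paste(reasons, collapse = ";"))
  }
  out
}
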