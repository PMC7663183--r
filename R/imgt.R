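# IMGT-style annotation of Fab chains into 28 substructures: per variable
# domain 4 framework regions + 3 CDRs, per constant domain 7 beta strands.
# The variable-domain numbering is an anchor-plus-gap-rule algorithm: the four
# conserved residues (Cys23, Trp41, Cys104, Phe/Trp118) are located by
# windowed scans and loop gaps are placed middle-out. All internal coordinates
# are 0-based half-open; user-facing tables are 1-based inclusive.

# IMGT delimitations on the 128-position variable-domain frame.
IMGT_REGION_BOUNDS <- list(
  FR1  = c(1L, 26L), CDR1 = c(27L, 38L), FR2 = c(39L, 55L),
  CDR2 = c(56L, 65L), FR3 = c(66L, 104L), CDR3 = c(105L, 117L),
  FR4  = c(118L, 128L)
)

#' Construct a Fab chain sequence
#'
#' @param residues One-letter amino-acid string (whitespace and case are
#'   normalised). Ambiguity codes (B, Z, X, ...) are rejected: every
#'   downstream descriptor table is defined only for the 20 canonical
#'   residues.
#' @param chain_id `"heavy"` or `"light"`.
#' @param v_domain_end 0-based exclusive index separating the variable from
#'   the constant domain. If `NULL`, inferred by assuming the chain ends with
#'   the packaged constant-domain allele (IGHG1*01 CH1 for heavy, kappa CL
#'   for light).
#' @return A `chain_sequence` object.
#' @export
chain_sequence <- function(residues, chain_id = c("heavy", "light"),
                           v_domain_end = NULL) {
  chain_id <- match.arg(chain_id)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  .assert_canonical(residues, paste(chain_id, "chain"))
  n <- nchar(residues)
  if (is.null(v_domain_end)) {
    const_len <- nchar(if (chain_id == "heavy") IGHG1_CH1 else IGKC_CL)
    v_domain_end <- n - const_len
  }
  if (v_domain_end <= 0L || v_domain_end >= n) {
    stop("v_domain_end must lie strictly inside the chain (got ",
         v_domain_end, " for length ", n, ")")
  }
  structure(list(chain_id = chain_id, residues = residues,
                 v_domain_end = as.integer(v_domain_end)),
            class = "chain_sequence")
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("<chain_sequence> %s, %d residues (V domain 1-%d)\n",
              x$chain_id, nchar(x$residues), x$v_domain_end))
  invisible(x)
}

# Middle-out slot assignment: keep the first ceil(L/2) and last floor(L/2) of
# `slots`, leaving the gap in the middle of the loop.
.middle_out <- function(slots, L) {
  if (L > length(slots)) stop("more residues than slots")
  if (L == 0L) return(integer(0))
  left <- ceiling(L / 2); right <- L - left
  c(slots[seq_len(left)],
    if (right > 0) slots[seq.int(length(slots) - right + 1L, length(slots))])
}

#' Number a variable-domain sequence on the IMGT frame
#'
#' Assigns residues to IMGT positions 1-128 by locating the four conserved
#' anchors (Cys23, Trp41, Cys104 and the J-region Phe/Trp118) with windowed
#' scans, then placing loop gaps middle-out. CDR3 loops longer than the
#' 13-position 105-117 window receive insertion labels (111.1, ..., 112.1)
#' between positions 111 and 112.
#'
#' @param seq Variable-domain amino-acid string (90-140 residues).
#' @param chain_kind `"heavy"` or `"kappa"`.
#' @return An `imgt_numbering` object: a named integer vector mapping IMGT
#'   position labels to 0-based residue indices, with the sequence and anchor
#'   indices attached.
#' @export
number_v_domain <- function(seq, chain_kind = c("heavy", "kappa")) {
  chain_kind <- match.arg(chain_kind)
  seq <- toupper(gsub("[[:space:]]", "", seq))
  .assert_canonical(seq, "V domain")
  n <- nchar(seq)
  if (n < 90L || n > 140L) {
    stop("LengthOutOfRange: V-domain length ", n, " outside plausible 90-140")
  }
  res <- strsplit(seq, "")[[1]]

  # Cys23: first C among residue indices 16..23 (1-based; at most 22
  # residues may precede IMGT position 23).
  c23 <- which(res[16:23] == "C")
  if (!length(c23)) stop("AnchorNotFound: Cys23 not located in FR1 window")
  c23 <- 15L + c23[1]

  # Trp41: CDR1 length L1 = w41 - c23 - 6 constrained to 2..12.
  w_cand <- which(res == "W")
  w_cand <- w_cand[w_cand - c23 - 6L >= 2L & w_cand - c23 - 6L <= 12L]
  if (!length(w_cand)) stop("AnchorNotFound: Trp41 not located after CDR1")
  w41 <- w_cand[1]
  L1 <- w41 - c23 - 6L

  # J anchor (Phe/Trp 118) sits 11 residues from the chain end.
  a118 <- n - 10L
  if (!res[a118] %in% c("F", "W")) {
    stop("AnchorNotFound: Phe/Trp118 not found at J-region anchor position")
  }

  # Cys104: CDR2 length L2 = c104 - w41 - 53 in 0..10; CDR3 length
  # L3 = a118 - c104 - 1 in 2..30 must be jointly consistent.
  c_cand <- which(res == "C")
  c_cand <- c_cand[c_cand - w41 - 53L >= 0L & c_cand - w41 - 53L <= 10L &
                   a118 - c_cand - 1L >= 2L & a118 - c_cand - 1L <= 30L]
  if (!length(c_cand)) stop("AnchorNotFound: Cys104 not located before CDR3")
  c104 <- c_cand[1]
  L2 <- c104 - w41 - 53L
  L3 <- a118 - c104 - 1L

  # Assemble the position -> 0-based residue index map.
  c23_0 <- c23 - 1L; w41_0 <- w41 - 1L; c104_0 <- c104 - 1L; a118_0 <- a118 - 1L
  labels <- character(0); idx <- integer(0)
  add <- function(lab, i) { labels <<- c(labels, lab); idx <<- c(idx, i) }

  # FR1: residues up to Cys23 right-aligned on positions ..23, then 24-26.
  add(as.character(seq.int(24L - c23, 23L)), seq_len(c23) - 1L)
  add(as.character(24:26), c23_0 + 1:3)
  # CDR1 on 27..38, middle-out.
  add(as.character(.middle_out(27:38, L1)), c23_0 + 3L + seq_len(L1))
  # 39-41 anchored on Trp41; FR2 42-55.
  add(as.character(39:41), w41_0 - 2L + 0:2)
  add(as.character(42:55), w41_0 + 1:14)
  # CDR2 on 56..65, middle-out (may be empty).
  if (L2 > 0L) add(as.character(.middle_out(56:65, L2)), w41_0 + 14L + seq_len(L2))
  # FR3 right-aligned to end at Cys104 (position 104).
  n_fr3 <- c104_0 - (w41_0 + 14L + L2)
  add(as.character(seq.int(105L - n_fr3, 104L)), c104_0 - n_fr3 + seq_len(n_fr3))
  # CDR3 on 105..117, insertion labels 111.x / 112.x beyond 13 residues.
  if (L3 <= 13L) {
    add(as.character(.middle_out(105:117, L3)), c104_0 + seq_len(L3))
  } else {
    extra <- L3 - 13L
    left_ins <- ceiling(extra / 2); right_ins <- extra - left_ins
    labs <- c(as.character(105:111),
              if (left_ins > 0) paste0("111.", seq_len(left_ins)),
              if (right_ins > 0) paste0("112.", rev(seq_len(right_ins))),
              as.character(112:117))
    add(labs, c104_0 + seq_len(L3))
  }
  # FR4: 118..128 (11 residues) anchored at the J Phe/Trp.
  add(as.character(118:128), a118_0 + seq_len(11L) - 1L)

  numbering <- idx; names(numbering) <- labels
  if (length(numbering) != n || any(sort(numbering) != 0:(n - 1L))) {
    stop("AnchorNotFound: anchors found but inconsistent with sequence length")
  }
  structure(numbering,
            sequence = seq, chain_kind = chain_kind,
            anchors = c(Cys23 = c23_0, Trp41 = w41_0,
                        Cys104 = c104_0, PheTrp118 = a118_0),
            class = "imgt_numbering")
}

# Base IMGT position of a (possibly inserted) label, e.g. "111.3" -> 111.
.base_pos <- function(labels) as.integer(sub("\\..*$", "", labels))

#' Extract CDR and framework regions from an IMGT numbering
#'
#' Cuts the numbered variable domain into its 7 regions (FR1, CDR1, FR2,
#' CDR2, FR3, CDR3, FR4) using the IMGT delimitations (CDR1 27-38, CDR2
#' 56-65, CDR3 105-117). Region names carry the chain letter, e.g. `CDR-H3`.
#' The regions tile the input: their sequences concatenate to the domain.
#'
#' @param numbering An `imgt_numbering` from [number_v_domain()].
#' @return A data.frame with columns region, start, end (0-based half-open)
#'   and sequence.
#' @export
extract_v_regions <- function(numbering) {
  stopifnot(inherits(numbering, "imgt_numbering"))
  seq <- attr(numbering, "sequence")
  letter <- if (attr(numbering, "chain_kind") == "heavy") "H" else "L"
  base <- .base_pos(names(numbering))
  out <- lapply(names(IMGT_REGION_BOUNDS), function(rn) {
    b <- IMGT_REGION_BOUNDS[[rn]]
    ids <- sort(unname(numbering[base >= b[1] & base <= b[2]]))
    num <- sub("(FR|CDR)", "", rn)
    kind <- sub("[0-9]+$", "", rn)
    name <- paste0(kind, "-", letter, num)
    if (!length(ids)) {
      return(data.frame(region = name, start = NA_integer_, end = NA_integer_,
                        sequence = "", stringsAsFactors = FALSE))
    }
    if (any(diff(ids) != 1L)) stop("region residues not contiguous: ", rn)
    data.frame(region = name, start = ids[1], end = ids[length(ids)] + 1L,
               sequence = substr(seq, ids[1] + 1L, ids[length(ids)] + 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the seven constant-domain strands
#'
#' Slices a constant-domain sequence into the seven beta strands A-G using
#' the packaged boundary table for the IGHG1*01 CH1 / kappa CL alleles. The
#' sequence must have exactly the allele template length (constant domains
#' are invariant across the IgG1-kappa Fabs in scope).
#'
#' @param seq Constant-domain amino-acid string.
#' @param domain_kind `"CH1"` or `"CL"`.
#' @return data.frame with columns region, start, end, sequence.
#' @export
extract_c_strands <- function(seq, domain_kind = c("CH1", "CL")) {
  domain_kind <- match.arg(domain_kind)
  seq <- toupper(gsub("[[:space:]]", "", seq))
  .assert_canonical(seq, paste(domain_kind, "domain"))
  template <- if (domain_kind == "CH1") IGHG1_CH1 else IGKC_CL
  if (nchar(seq) != nchar(template)) {
    stop("LengthMismatch: ", domain_kind, " length ", nchar(seq),
         " does not match the packaged allele length ", nchar(template))
  }
  b <- C_STRAND_BOUNDS[[domain_kind]]
  data.frame(
    region   = paste0("strand-", domain_kind, "-", b$strand),
    start    = b$start,
    end      = b$end,
    sequence = substring(seq, b$start + 1L, b$end),
    stringsAsFactors = FALSE
  )
}

#' Annotate a Fab into its 28 IMGT substructures
#'
#' Numbers both variable domains, extracts 3 CDRs + 4 FRs per variable
#' domain and 7 strands per constant domain: 28 regions in total, with the
#' conserved anchor indices recorded per chain. Deterministic.
#'
#' @param heavy,light [chain_sequence()] objects.
#' @return A `fab_annotation`: data.frame with columns chain, region, start,
#'   end (0-based half-open, on the full chain) and sequence, with an
#'   `anchors` attribute.
#' @export
annotate_fab <- function(heavy, light) {
  stopifnot(inherits(heavy, "chain_sequence"), inherits(light, "chain_sequence"),
            heavy$chain_id == "heavy", light$chain_id == "light")
  one_chain <- function(ch, kind, cdom) {
    v_seq <- substr(ch$residues, 1L, ch$v_domain_end)
    c_seq <- substr(ch$residues, ch$v_domain_end + 1L, nchar(ch$residues))
    num <- number_v_domain(v_seq, kind)
    v <- extract_v_regions(num)
    s <- extract_c_strands(c_seq, cdom)
    s$start <- s$start + ch$v_domain_end
    s$end <- s$end + ch$v_domain_end
    df <- rbind(v, s)
    df <- cbind(chain = if (kind == "heavy") "H" else "L", df,
                stringsAsFactors = FALSE)
    list(regions = df, anchors = attr(num, "anchors"))
  }
  h <- one_chain(heavy, "heavy", "CH1")
  l <- one_chain(light, "kappa", "CL")
  regions <- rbind(h$regions, l$regions)
  rownames(regions) <- NULL
  if (nrow(regions) != 28L) stop("annotation did not produce 28 regions")
  anchors <- c(stats::setNames(h$anchors, paste0("H.", names(h$anchors))),
               stats::setNames(l$anchors, paste0("L.", names(l$anchors))))
  structure(regions, anchors = anchors,
            chains = list(H = heavy, L = light),
            class = c("fab_annotation", "data.frame"))
}

#' Read paired Fab chains from FASTA
#'
#' Record ids must follow `<sample>_<H|L>`; each sample needs both chains.
#'
#' @param path FASTA file with both chains per sample (or two files given as
#'   a character vector, e.g. separate heavy and light files).
#' @return Named list (by sample) of lists with elements `heavy`, `light`.
#' @export
read_chain_fasta <- function(path) {
  recs <- do.call(c, lapply(path, Biostrings::readAAStringSet))
  ids <- sub("\\s.*$", "", names(recs))
  m <- regmatches(ids, regexec("^(.*)_([HL])$", ids))
  if (any(lengths(m) != 3L)) {
    stop("FASTA ids must look like '<sample>_H' or '<sample>_L'")
  }
  samples <- vapply(m, `[`, "", 2L)
  chains <- vapply(m, `[`, "", 3L)
  out <- list()
  for (s in unique(samples)) {
    hi <- which(samples == s & chains == "H")
    li <- which(samples == s & chains == "L")
    if (length(hi) != 1L || length(li) != 1L) {
      stop("sample '", s, "' must have exactly one H and one L record")
    }
    out[[s]] <- list(heavy = chain_sequence(as.character(recs[[hi]]), "heavy"),
                     light = chain_sequence(as.character(recs[[li]]), "light"))
  }
  out
}

#' Write / read a region annotation table
#'
#' The interchange format is a tab-separated table with columns sample,
#' chain, region, start, end, sequence; coordinates are 1-based inclusive in
#' the file and converted back to the internal 0-based half-open convention
#' on read, so the round trip is the identity.
#'
#' @param annotations Named list of `fab_annotation` objects (names are
#'   sample ids), or a single annotation (sample id `"sample1"`).
#' @param path Output TSV path.
#' @return `write_region_table`: the path, invisibly. `read_region_table`:
#'   named list of `fab_annotation` objects.
#' @export
write_region_table <- function(annotations, path) {
  if (inherits(annotations, "fab_annotation")) {
    annotations <- list(sample1 = annotations)
  }
  rows <- lapply(names(annotations), function(s) {
    a <- annotations[[s]]
    data.frame(sample = s, chain = a$chain, region = a$region,
               start = a$start + 1L, end = a$end, sequence = a$sequence,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(df$sample)) {
    d <- df[df$sample == s, c("chain", "region", "start", "end", "sequence")]
    d$start <- d$start - 1L
    rownames(d) <- NULL
    out[[s]] <- structure(d, class = c("fab_annotation", "data.frame"))
  }
  out
}
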