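# Seq2D descriptors: per-region sums of amino-acid-scale components, summed
# per-residue property tables, and pepstats-like physicochemical properties.
# Only the variable-domain regions enter the Seq2D matrix: the constant
# domains are sequence-invariant across IgG1-kappa Fabs, so their sequence
# descriptors would be static.

#' Construct an amino-acid property scale
#'
#' @param name Scale identifier (used in descriptor names).
#' @param table 20 x k numeric matrix, rows named by one-letter residue
#'   codes, columns named by component.
#' @return A `property_scale` object.
#' @export
property_scale <- function(name, table) {
  table <- as.matrix(table)
  if (!all(AA_LETTERS %in% rownames(table)) || any(!is.finite(table))) {
    stop("scale table must have finite values for all 20 canonical residues")
  }
  structure(list(name = name, components = colnames(table),
                 table = table[AA_LETTERS, , drop = FALSE]),
            class = "property_scale")
}

#' Sum scale components over a region sequence
#'
#' For each component c of the scale, returns the sum over the region's
#' residues of the tabulated value. An empty region gives a zero vector.
#'
#' @param region_seq Amino-acid string (canonical letters only).
#' @param scale A [property_scale()].
#' @return Named numeric vector, one entry per scale component.
#' @export
scale_region_sum <- function(region_seq, scale) {
  stopifnot(inherits(scale, "property_scale"))
  if (!nchar(region_seq)) {
    return(stats::setNames(numeric(length(scale$components)), scale$components))
  }
  .assert_canonical(region_seq, "region")
  res <- strsplit(region_seq, "")[[1]]
  colSums(scale$table[res, , drop = FALSE])
}

#' Sum a registered per-residue property over a region
#'
#' @param region_seq Amino-acid string; empty regions sum to 0.
#' @param table_name Name of a registered table (see [residue_tables()]).
#' @return Scalar sum.
#' @export
residue_property_sum <- function(region_seq, table_name) {
  tab <- residue_tables(table_name)
  if (!nchar(region_seq)) return(0)
  .assert_canonical(region_seq, "region")
  sum(tab[strsplit(region_seq, "")[[1]]])
}

# Henderson-Hasselbalch net charge at a given pH, EMBOSS-style pKa set.
.net_charge_at_ph <- function(counts, ph) {
  pos <- function(pk, n) n / (1 + 10^(ph - pk))
  neg <- function(pk, n) -n / (1 + 10^(pk - ph))
  pos(PKA_TABLE$nterm, 1) + neg(PKA_TABLE$cterm, 1) +
    pos(PKA_TABLE$H, counts["H"]) + pos(PKA_TABLE$K, counts["K"]) +
    pos(PKA_TABLE$R, counts["R"]) +
    neg(PKA_TABLE$D, counts["D"]) + neg(PKA_TABLE$E, counts["E"]) +
    neg(PKA_TABLE$C, counts["C"]) + neg(PKA_TABLE$Y, counts["Y"])
}

#' Pepstats-like physicochemical properties of a peptide
#'
#' Deterministic properties computed from packaged constants: molecular
#' weight (average residue masses + one water, Da), net charge at pH 7 (e),
#' isoelectric point (bisection on the Henderson-Hasselbalch net-charge
#' function, tolerance 1e-4 pH), Ikai aliphatic index, and the EMBOSS
#' residue-class mole fractions (tiny, small, aromatic, polar, nonpolar).
#'
#' @param region_seq Non-empty amino-acid string.
#' @return Named numeric vector of 9 properties.
#' @export
pepstats_like <- function(region_seq) {
  if (!nchar(region_seq)) stop("EmptyRegion: pepstats properties need residues")
  .assert_canonical(region_seq, "region")
  res <- strsplit(region_seq, "")[[1]]
  n <- length(res)
  counts <- stats::setNames(tabulate(factor(res, AA_LETTERS), 20), AA_LETTERS)

  mw <- sum(AA_RESIDUE_MASS[res]) + MASS_WATER
  charge7 <- .net_charge_at_ph(counts, 7)

  # Bisection for the isoelectric point; the charge function is monotone
  # decreasing in pH.
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  pi_val <- (lo + hi) / 2

  ai <- 100 * (counts["A"] + 2.9 * counts["V"] +
               3.9 * (counts["I"] + counts["L"])) / n
  frac <- vapply(AA_CLASS, function(cls) sum(counts[cls]) / n, 0)

  c(molecular_weight = unname(mw),
    net_charge = unname(charge7),
    isoelectric_point = pi_val,
    aliphatic_index = unname(ai),
    tiny_fraction = unname(frac["tiny"]),
    small_fraction = unname(frac["small"]),
    aromatic_fraction = unname(frac["aromatic"]),
    polar_fraction = unname(frac["polar"]),
    nonpolar_fraction = unname(frac["nonpolar"]))
}

.is_v_region <- function(region) grepl("^(FR|CDR)-", region)

#' Build the Seq2D descriptor table
#'
#' Assembles the sequence-level descriptor matrix over the 14 variable-domain
#' regions (7 per chain): per-region scale-component sums for each enabled
#' scale, summed registered residue-property tables, and optionally the
#' pepstats-like property block. Constant-domain strand regions are excluded
#' by construction. Descriptor names follow `<region>.<scale>.<component>`.
#' Empty regions contribute zeros (with a warning) so the matrix stays
#' rectangular.
#'
#' @param annotations Named list of `fab_annotation` objects; names become
#'   sample ids (an unnamed list gets `sample1..n`).
#' @param scales Named list of [property_scale()] objects; default all
#'   packaged scales ([aa_scales()]).
#' @param residue_table_names Registered table names to sum per region.
#' @param pepstats Include the pepstats-like block (skipping empty regions'
#'   undefined properties by emitting zeros).
#' @return A `descriptor_table`: numeric matrix (samples x descriptors) with
#'   attribute `provenance = "Seq2D"`.
#' @export
build_seq2d <- function(annotations, scales = aa_scales(),
                        residue_table_names = residue_tables(),
                        pepstats = TRUE) {
  if (inherits(annotations, "fab_annotation")) annotations <- list(annotations)
  if (is.null(names(annotations))) {
    names(annotations) <- paste0("sample", seq_along(annotations))
  }
  rows <- lapply(annotations, function(a) {
    v <- a[.is_v_region(a$region), , drop = FALSE]
    if (nrow(v) != 14L) stop("expected 14 variable-domain regions, got ", nrow(v))
    vals <- c(); nms <- c()
    for (i in seq_len(nrow(v))) {
      rg <- v$region[i]; sq <- v$sequence[i]
      if (!nchar(sq)) warning("empty region ", rg, ": emitting zero descriptors")
      for (sc in scales) {
        x <- scale_region_sum(sq, sc)
        vals <- c(vals, x)
        nms <- c(nms, paste(rg, sc$name, names(x), sep = "."))
      }
      for (tn in residue_table_names) {
        vals <- c(vals, residue_property_sum(sq, tn))
        nms <- c(nms, paste(rg, tn, "sum", sep = "."))
      }
      if (pepstats) {
        x <- if (nchar(sq)) pepstats_like(sq) else
          stats::setNames(numeric(9), names(pepstats_like("A")))
        vals <- c(vals, x)
        nms <- c(nms, paste(rg, "pepstats", names(x), sep = "."))
      }
    }
    stats::setNames(vals, nms)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(annotations)
  descriptor_table(mat, provenance = "Seq2D")
}

#' Descriptor table container
#'
#' A samples x descriptors numeric matrix with unique descriptor names,
#' finite values and a provenance tag (`Seq2D`, `Hom3D` or `MD3D`).
#'
#' @param values Numeric matrix with row names (sample ids) and column names
#'   (descriptor names).
#' @param provenance One of `"Seq2D"`, `"Hom3D"`, `"MD3D"`.
#' @return A `descriptor_table` (matrix subclass).
#' @export
descriptor_table <- function(values, provenance = c("Seq2D", "Hom3D", "MD3D")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (anyDuplicated(colnames(values))) stop("duplicate descriptor names")
  if (any(!is.finite(values))) stop("descriptor values must be finite")
  structure(values, provenance = provenance,
            class = c("descriptor_table", class(values)))
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table> %s: %d samples x %d descriptors\n",
              attr(x, "provenance"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write / read a descriptor table as CSV
#'
#' Samples in rows (first column `sample`), descriptors in columns; the
#' interchange format consumed by the chemometrics module.
#' @param table A [descriptor_table()].
#' @param path CSV path.
#' @param provenance Provenance tag to attach on read.
#' @return The path (write) or a `descriptor_table` (read).
#' @export
write_descriptor_csv <- function(table, path) {
  df <- data.frame(sample = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path, provenance = "Seq2D") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  descriptor_table(m, provenance = provenance)
}
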