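#' @include AllClasses.R
NULL

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "mitocompart", mustWork = TRUE)
}

#' Chou-Fasman helix and sheet propensities
#'
#' Loads the classical Chou-Fasman conformational propensity table shipped
#' with the package (or an alternative table of the same layout).
#'
#' @param path TSV with columns `aa`, `helix`, `sheet`; default the
#'   bundled table.
#' @return Numeric matrix with rows `helix`, `sheet` and one column per
#'   amino acid in [AA_ALPHABET20] order.
#' @export
chouFasmanTable <- function(path = pkg_extdata("chou_fasman.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "helix", "sheet") %in% names(tab)))
    stop("propensity table needs columns aa, helix, sheet", call. = FALSE)
  if (!setequal(tab$aa, AA_ALPHABET20))
    stop("propensity table must cover the 20 standard amino acids",
         call. = FALSE)
  i <- match(AA_ALPHABET20, tab$aa)
  rbind(helix = stats::setNames(tab$helix[i], AA_ALPHABET20),
        sheet = stats::setNames(tab$sheet[i], AA_ALPHABET20))
}

.read_groups <- function(path, key = "group") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(tab$members, ""), tab[[key]])
}

#' Default amino-acid grouping scheme
#'
#' Loads the bundled group definitions: 10 functional groups by side-chain
#' chemistry (aliphatic, hydroxyl, sulfur-containing, aromatic, basic,
#' acidic, amide, imino, tiny, charged), 7 physico-chemical groups
#' (hydrophobic, hydrophilic, neutral, polar, non-polar, small, aromatic)
#' and 5 disjoint short-peptide residue classes. All memberships live in
#' TSV resources under `inst/extdata` and can be overridden.
#'
#' @param functionalPath,physchemPath,peptidePath Optional alternative TSV
#'   paths (columns `group`/`class` and `members`).
#' @return A [GroupingScheme-class].
#' @export
defaultGroupingScheme <- function(
    functionalPath = pkg_extdata("functional_groups.tsv"),
    physchemPath = pkg_extdata("physchem_groups.tsv"),
    peptidePath = pkg_extdata("peptide_classes.tsv")) {
  new("GroupingScheme",
      functionalGroups = .read_groups(functionalPath),
      physchemGroups = .read_groups(physchemPath),
      peptideClasses = .read_groups(peptidePath, key = "class"))
}

# AAindex accessions behind the default 31-scale physicochemical block.
.default_scale_accessions <- c(
  "KYTJ820101",  # hydropathy (Kyte-Doolittle)
  "HOPT810101",  # hydrophilicity (Hopp-Woods)
  "EISD840101",  # consensus hydrophobicity (Eisenberg)
  "FASG760101",  # molecular weight
  "ZIMJ680102",  # bulkiness
  "ZIMJ680103",  # polarity (Zimmerman)
  "ZIMJ680104",  # isoelectric point
  "GRAR740102",  # polarity (Grantham)
  "GRAR740103",  # volume (Grantham)
  "BHAR880101",  # flexibility (Bhaskaran-Ponnuswamy)
  "CHAM820101",  # polarizability
  "CHAM820102",  # free energy of solution in water
  "CHOC760101",  # residue accessible surface area
  "CHOC760102",  # accessible surface area in folded protein
  "JANJ780101",  # average accessible surface area
  "FAUJ880103",  # normalized van der Waals volume
  "FAUJ880109",  # number of hydrogen-bond donors
  "FAUJ880110",  # number of full nonbonded orbitals
  "DAYM780101",  # amino-acid composition (Dayhoff)
  "KRIW790101",  # side-chain interaction parameter
  "LEVM760101",  # hydrophobic parameter (Levitt)
  "MANP780101",  # average surrounding hydrophobicity
  "PONP800101",  # surrounding hydrophobicity in folded form
  "RADA880108",  # mean polarity
  "ROSG850101",  # mean area buried on transfer
  "ROSG850102",  # mean fractional area loss
  "WOLS870101",  # principal property value z1
  "BULH740101",  # transfer free energy to surface
  "BIGC670101",  # residue volume (Bigelow)
  "COHE430101",  # partial specific volume
  "OOBM770101")  # average nonbonded energy per atom

# AAindex tables list residues in ARNDCQEGHILKMFPSTWYV order.
.aaindex_order <- c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V")

#' Default physicochemical property scales
#'
#' Builds the 31-scale physicochemical block from the AAindex database
#' bundled with the seqinr package (hydropathy, hydrophilicity, bulkiness,
#' polarity, volume, flexibility, accessible surface area, and related
#' per-residue properties). Which 31 properties to use is a package
#' convention and can be overridden with any accession subset or an
#' external TSV ([readPhyschemScales()]).
#'
#' @param accessions Character vector of 31 AAindex accession numbers.
#' @return A [PhyschemScales-class].
#' @export
defaultPhyschemScales <- function(accessions = .default_scale_accessions) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  missing <- setdiff(accessions, names(aaindex))
  if (length(missing))
    stop("unknown AAindex accession(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- t(vapply(aaindex[accessions], function(e) {
    v <- stats::setNames(as.numeric(e$I), .aaindex_order)
    if (anyNA(v))
      stop("AAindex entry with missing residue values: ", e$H,
           call. = FALSE)
    v[AA_ALPHABET20]
  }, numeric(20)))
  rownames(vals) <- accessions
  colnames(vals) <- AA_ALPHABET20
  new("PhyschemScales", values = vals)
}

#' Read physicochemical scales from a TSV resource
#'
#' @param path TSV with a `scale` column followed by 20 amino-acid columns
#'   (one-letter codes).
#' @return A [PhyschemScales-class].
#' @export
readPhyschemScales <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"scale" %in% names(tab))
    stop("scale table needs a 'scale' column", call. = FALSE)
  miss <- setdiff(AA_ALPHABET20, names(tab))
  if (length(miss))
    stop("scale table missing residue column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  vals <- as.matrix(tab[, AA_ALPHABET20])
  rownames(vals) <- tab$scale
  new("PhyschemScales", values = vals)
}

#' Write physicochemical scales to TSV
#'
#' @param scales A [PhyschemScales-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writePhyschemScales <- function(scales, path) {
  stopifnot(is(scales, "PhyschemScales"))
  tab <- data.frame(scale = rownames(scales@values),
                    scales@values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
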