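#' SNP panel constructor
#'
#' A SNP panel holds the site coordinates shared by all genotype matrices:
#' chromosome label, physical position (1-based, as in EIGENSTRAT `.snp`
#' files), genetic position in Morgans, and the two alleles. Positions must
#' be strictly increasing and genetic positions non-decreasing within each
#' chromosome.
#'
#' @param chrom character vector of chromosome labels (autosomes "1".."22")
#' @param pos integer vector of physical positions (base pairs, 1-based)
#' @param gpos numeric vector of genetic positions (Morgans)
#' @param ref,alt single-character alleles (A/C/G/T), distinct per site
#' @return a `data.frame` of class `snp_panel` with one row per site
#' @export
snp_panel <- function(chrom, pos, gpos, ref, alt) {
  n <- length(chrom)
  if (!all(lengths(list(pos, gpos, ref, alt)) == n))
    stop_pmrkin("snp_panel: field lengths differ")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  gpos <- as.numeric(gpos)
  bad <- !chrom %in% as.character(1:22)
  if (any(bad))
    stop_pmrkin("snp_panel: unknown chromosome label '%s'", chrom[which(bad)[1]])
  if (any(ref == alt))
    stop_pmrkin("snp_panel: ref and alt alleles identical at site %d",
                which(ref == alt)[1])
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    if (is.unsorted(pos[idx], strictly = TRUE))
      stop_pmrkin("snp_panel: positions not strictly increasing on chromosome %s", ch)
    if (is.unsorted(gpos[idx]))
      stop_pmrkin("snp_panel: genetic positions decrease on chromosome %s", ch)
  }
  out <- data.frame(chrom = chrom, pos = pos, gpos = gpos,
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_panel", "data.frame")
  out
}

# map EIGENSTRAT digits to pseudo-haploid calls.
# Pseudo-haploid convention: 2 = two REF alleles -> REF (0), 0 = ALT (1),
# 9 = missing. A genuine heterozygote (1) cannot occur in pseudo-haploid
# data and is rejected unless het = "random".
decode_geno_digits <- function(digits, het = c("error", "random")) {
  het <- match.arg(het)
  calls <- rep(NA_integer_, length(digits))
  calls[digits == 2L] <- 0L
  calls[digits == 0L] <- 1L
  ishet <- digits == 1L
  if (any(ishet)) {
    if (het == "error")
      stop_pmrkin(paste0("heterozygous genotype '1' found: data are not ",
                         "pseudo-haploid (use het = \"random\" to sample an allele)"))
    warning(sprintf("%d heterozygous calls mapped to a random allele", sum(ishet)),
            call. = FALSE)
    calls[ishet] <- sample(c(0L, 1L), sum(ishet), replace = TRUE)
  }
  bad <- !digits %in% c(0L, 1L, 2L, 9L)
  if (any(bad))
    stop_pmrkin("invalid genotype digit '%s'", digits[which(bad)[1]])
  calls
}

#' Read an EIGENSTRAT genotype trio
#'
#' Reads `.geno` / `.snp` / `.ind` files into a SNP panel and a
#' pseudo-haploid call matrix (individuals in rows, sites in columns;
#' values 0 = REF, 1 = ALT, `NA` = missing). Genotype digit 2 maps to REF,
#' 0 to ALT and 9 to missing; a genuine heterozygote digit 1 is rejected
#' unless `het = "random"`.
#'
#' @param prefix path prefix: `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#' @param het how to treat heterozygote digits ("error" or "random")
#' @return list with elements `panel` (snp_panel), `geno` (integer matrix
#'   with individual ids as rownames) and `ind` (data.frame id, sex, group)
#' @export
read_eigenstrat <- function(prefix, het = c("error", "random")) {
  het <- match.arg(het)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop_pmrkin("file not found: %s", p)

  snp <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "chrom", "gpos", "pos", "ref", "alt"))
  ind <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "group"))
  lines <- readLines(paths[1])
  if (length(lines) == 0L) stop_pmrkin("%s: no sites", paths[1])
  if (length(lines) != nrow(snp))
    stop_pmrkin(".geno has %d rows but .snp has %d", length(lines), nrow(snp))
  w <- nchar(lines)
  if (any(w != nrow(ind)))
    stop_pmrkin(".geno row width %d does not match %d individuals in .ind",
                w[which(w != nrow(ind))[1]], nrow(ind))

  digits <- matrix(utf8ToInt(paste(lines, collapse = "")) - utf8ToInt("0"),
                   nrow = nrow(ind))  # sites in columns after this fill
  if (any(digits < 0L | digits > 9L))
    stop_pmrkin(".geno contains non-digit characters")
  geno <- matrix(decode_geno_digits(as.integer(digits), het = het),
                 nrow = nrow(ind), dimnames = list(ind$id, NULL))
  panel <- snp_panel(snp$chrom, snp$pos, snp$gpos, snp$ref, snp$alt)
  list(panel = panel, geno = geno, ind = ind)
}

sex_to_ind_code <- function(sex) {
  c(XX = "F", XY = "M", INDETERMINATE = "U")[sex]
}

ind_code_to_sex <- function(code) {
  c(F = "XX", M = "XY", U = "INDETERMINATE")[code]
}

#' Write an EIGENSTRAT genotype trio
#'
#' Inverse of [read_eigenstrat()]: REF encodes as 2, ALT as 0, missing as 9.
#' Sex is written to the `.ind` file as F (XX), M (XY) or U (indeterminate).
#'
#' @param panel a [snp_panel()]
#' @param geno individuals x sites matrix of calls (0/1/NA)
#' @param sex character vector of XX/XY/INDETERMINATE, one per individual
#'   (defaults to indeterminate)
#' @param prefix output path prefix
#' @param group population label written to the third `.ind` column
#' @return invisibly, the three file paths
#' @export
write_eigenstrat <- function(panel, geno, prefix, sex = NULL, group = "POP1") {
  if (ncol(geno) != nrow(panel))
    stop_pmrkin("geno has %d sites but panel has %d", ncol(geno), nrow(panel))
  ids <- rownames(geno)
  if (is.null(ids)) stop_pmrkin("geno must have individual ids as rownames")
  if (is.null(sex)) sex <- rep("INDETERMINATE", nrow(geno))

  digit <- matrix("9", nrow = nrow(geno), ncol = ncol(geno))
  digit[!is.na(geno) & geno == 0L] <- "2"
  digit[!is.na(geno) & geno == 1L] <- "0"
  # .geno rows are sites; each row one character per individual
  lines <- apply(digit, 2, paste, collapse = "")

  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(lines, paths[1])
  snp <- data.frame(id = paste0("snp", seq_len(nrow(panel))),
                    chrom = panel$chrom,
                    gpos = format(panel$gpos, digits = 10, scientific = FALSE, trim = TRUE),
                    pos = panel$pos, ref = panel$ref, alt = panel$alt)
  utils::write.table(snp, paths[2], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  ind <- data.frame(id = ids, sex = sex_to_ind_code(sex), group = group)
  utils::write.table(ind, paths[3], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

METADATA_COLS <- c("id", "sex", "age_class", "age_min", "age_max",
                   "mt_hg", "y_hg", "grave_x", "grave_y")

#' Read a per-individual metadata table
#'
#' Tab-separated table with header; required columns `id` and `sex`
#' (XX/XY/INDETERMINATE). Optional columns: `age_class` (SUBADULT/ADULT),
#' `age_min`, `age_max` (years), `mt_hg`, `y_hg` (haplogroup labels),
#' `grave_x`, `grave_y` (metres). Blank optional fields become `NA`;
#' unknown columns are preserved. A Y haplogroup on an XX individual, a
#' duplicate id, or `age_min > age_max` is an error.
#'
#' @param path TSV file path
#' @return a `data.frame` with one row per individual
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_pmrkin("file not found: %s", path)
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  for (col in c("id", "sex"))
    if (!col %in% names(md)) stop_pmrkin("metadata: missing required column '%s'", col)
  if (anyDuplicated(md$id))
    stop_pmrkin("metadata: duplicate id '%s'", md$id[duplicated(md$id)][1])
  bad_sex <- !md$sex %in% c("XX", "XY", "INDETERMINATE")
  if (any(bad_sex)) stop_pmrkin("metadata: invalid sex '%s'", md$sex[bad_sex][1])
  for (col in setdiff(METADATA_COLS, names(md))) md[[col]] <- NA
  md$age_min <- as.numeric(md$age_min); md$age_max <- as.numeric(md$age_max)
  md$grave_x <- as.numeric(md$grave_x); md$grave_y <- as.numeric(md$grave_y)
  bad_y <- !is.na(md$y_hg) & md$sex == "XX"
  if (any(bad_y))
    stop_pmrkin("metadata: Y haplogroup given for XX individual '%s'", md$id[bad_y][1])
  bad_age <- !is.na(md$age_min) & !is.na(md$age_max) & md$age_min > md$age_max
  if (any(bad_age))
    stop_pmrkin("metadata: age_min > age_max for '%s'", md$id[bad_age][1])
  md
}

#' Write a metadata table readable by [read_metadata()]
#' @param md metadata data.frame
#' @param path output TSV path
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     na = "")
  invisible(path)
}
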