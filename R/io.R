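#' Read a mutation-effect table, applying dataset-specific filters
#'
#' Loads a TSV of per-mutation effects into a standard record layout
#' (`variant_id`, `region`, `starting_psi`, `delta_psi`, optional
#' `se_delta_psi`), applying the filtering conventions of the supported
#' dataset dialects:
#'
#' * `generic`: columns taken as-is, no filtering.
#' * `ron`: mini-gene saturation mutagenesis layout. Rows whose
#'   `class` column flags insertions (`IN`) or deletions (`DEL`) are
#'   dropped; the construct `position` column assigns regions — exon
#'   positions 298-444 are `exonic`, flanking introns 211-297 and 445-524
#'   `intronic`, everything else `other`.
#' * `sre` / `snv`: multiplexed-library layout with a `category` column;
#'   only whitelisted exonic/intronic categories are retained and
#'   repeated mutations of the same exon are aggregated to their median
#'   effect (one weight per exon), needing columns `exon_id`,
#'   `starting_psi`, `delta_psi`.
#' * `vexseq`: like `sre`/`snv` with the variant-category whitelist of
#'   that resource; no median aggregation (effects are already
#'   per-variant).
#'
#' Every load attaches a filter audit (`attr(, "audit")`): a data frame
#' of records dropped per rule, satisfying
#' `rows in = rows out + sum(drops)`.
#'
#' @param path TSV file (header row, tab-separated).
#' @param dialect one of `"generic"`, `"ron"`, `"sre"`, `"snv"`,
#'   `"vexseq"`.
#' @return data frame of effect records with the audit attached.
#' @export
load_effect_table <- function(path,
                              dialect = c("generic", "ron", "sre", "snv",
                                          "vexseq")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  n_in <- nrow(x)
  audit <- data.frame(rule = character(0), dropped = integer(0))
  note <- function(rule, k) rbind(audit, data.frame(rule = rule, dropped = k))

  need <- function(cols) {
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }

  if (dialect == "generic") {
    need(c("variant_id", "region", "starting_psi", "delta_psi"))
  } else if (dialect == "ron") {
    need(c("variant_id", "position", "starting_psi", "delta_psi"))
    if ("class" %in% names(x)) {
      drop <- x$class %in% c("IN", "DEL")
      audit <- note("indel_exclusion", sum(drop))
      x <- x[!drop, , drop = FALSE]
    }
    x$region <- ifelse(x$position >= 298 & x$position <= 444, "exonic",
                ifelse((x$position >= 211 & x$position <= 297) |
                       (x$position >= 445 & x$position <= 524), "intronic",
                       "other"))
  } else if (dialect %in% c("sre", "snv")) {
    need(c("exon_id", "category", "starting_psi", "delta_psi"))
    whitelist <- if (dialect == "sre") {
      c("clst_Ke2011_ESE", "rmv_Ke2011_ESE", "clst_Ke2011_ESS",
        "rmv_Ke2011_ESS", "rnd_exon_1nt", "rnd_exon_2nt", "rnd_exon_3nt",
        "rnd_exon_5nt", "aggr_exon",
        "clst_Vlkr07_AICS", "clst_Vlkr07_DICS", "rmv_Vlkr07_AICS",
        "rmv_Vlkr07_DICS", "rnd_intron_1nt", "rnd_intron_2nt",
        "rnd_intron_3nt", "rnd_intron_5nt", "aggr_intron", "p_aggr_intr")
    } else c("exon", "downstr_intron", "upstr_intron")
    drop <- !x$category %in% whitelist
    audit <- note("category_whitelist", sum(drop))
    x <- x[!drop, , drop = FALSE]
    x$region <- ifelse(grepl("exon", x$category), "exonic", "intronic")
    # median effect per repeatedly mutated exon, per region, so every
    # exon carries equal weight in the effect distribution
    agg <- stats::aggregate(
      cbind(delta_psi, starting_psi) ~ exon_id + region, data = x,
      FUN = stats::median)
    n_agg <- nrow(x) - nrow(agg)
    audit <- rbind(audit,
                   data.frame(rule = "median_aggregation", dropped = n_agg))
    agg$variant_id <- paste(agg$exon_id, agg$region, sep = ":")
    x <- agg
  } else if (dialect == "vexseq") {
    need(c("variant_id", "category", "starting_psi", "delta_psi"))
    whitelist <- c("frameshift", "inframe deletion", "missense",
                   "synonymous", "stop gained", "stop lost",
                   "non coding transcript exon", "intron")
    drop <- !x$category %in% whitelist
    audit <- note("category_whitelist", sum(drop))
    x <- x[!drop, , drop = FALSE]
    x$region <- ifelse(x$category == "intron", "intronic", "exonic")
  }

  keep <- c("variant_id", "region", "starting_psi", "delta_psi",
            intersect("se_delta_psi", names(x)),
            intersect(c("exon_id", "position"), names(x)))
  out <- x[, keep, drop = FALSE]
  rownames(out) <- NULL
  stopifnot(n_in == nrow(out) + sum(audit$dropped))
  attr(out, "audit") <- audit
  out
}

#' Write / read an effect table
#'
#' Plain TSV round trip for the standard effect-record layout; missing
#' values are serialised as `NA` and PSI stays on the 0-100 percent scale.
#'
#' @param effects effect-record data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a hexamer motif list (one 6-mer per line)
#'
#' @param path plain-text file, one hexamer per line; blank lines and
#'   lines starting with `#` are ignored.
#' @param role motif role label.
#' @return a [hexamer_set()].
#' @export
read_hexamers <- function(path, role = "ESE") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hexamer_set(lines, role = role)
}

#' @rdname read_hexamers
#' @param motifs a [hexamer_set()] to write.
#' @export
write_hexamers <- function(motifs, path) {
  writeLines(as.character(motifs), path)
  invisible(path)
}

#' Read exon sequences from FASTA
#'
#' @param path FASTA file with exon identifiers as headers.
#' @return data frame `exon_id`, `sequence`.
#' @export
read_exon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- data.frame(exon_id = names(seqs),
                    sequence = unname(as.character(seqs)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname read_exon_fasta
#' @param exons data frame with `exon_id` and `sequence` columns.
#' @export
write_exon_fasta <- function(exons, path) {
  seqs <- Biostrings::DNAStringSet(exons$sequence)
  names(seqs) <- exons$exon_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a PSI atlas as TSV
#'
#' Layout: `exon_id`, `chrom`, `start`, `end`, `strand`, `length`, then
#' one PSI column per tissue. Coordinates are 0-based half-open.
#'
#' @param atlas a [psi_atlas()].
#' @param path TSV path.
#' @return `path` (writer) / a `psi_atlas` (reader).
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "psi_atlas"))
  df <- cbind(atlas$exons, as.data.frame(atlas$psi))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  meta <- c("exon_id", "chrom", "start", "end", "strand", "length")
  tissues <- setdiff(names(df), meta)
  psi_atlas(df[intersect(meta, names(df))],
            as.matrix(df[tissues]))
}

#' Write / read DMS count tables as TSV
#'
#' @param counts count-table data frame ([score_variants()] layout).
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read a genotype dosage table from TSV
#'
#' Layout: variant metadata columns (`variant_id`, `exon_id`, `position`,
#'   `ref`, `alt`, `allele_frequency`, `region`, optionally
#'   `exon_midpoint`) followed by one column per sample holding allele
#'   copies (0/1/2, `NA` for missing).
#'
#' @param path TSV path.
#' @return a genotype table: list with `variants` and `copies`.
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  meta <- intersect(c("variant_id", "exon_id", "position", "exon_midpoint",
                      "ref", "alt", "allele_frequency", "region"),
                    names(df))
  samples <- setdiff(names(df), meta)
  copies <- as.matrix(df[samples])
  rownames(copies) <- df$variant_id
  list(variants = df[meta], copies = copies)
}

#' @rdname read_genotypes_tsv
#' @param genotypes genotype table to write.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$variants, as.data.frame(genotypes$copies))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read genotype copies from a minimal VCF
#'
#' Parses a VCF v4.2 subset (CHROM, POS, REF, ALT, GT) into the same
#' genotype-table layout as [read_genotypes_tsv()]. Positions are
#' converted from VCF 1-based to the package's 0-based convention.
#' Requires the `vcfR` package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return genotype table (list with `variants`, `copies`); region and
#'   exon assignment are left `NA` for the caller to annotate.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  copies <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
  })
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    exon_id = NA_character_,
    position = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT,
    allele_frequency = rowMeans(copies, na.rm = TRUE) / 2,
    region = NA_character_,
    stringsAsFactors = FALSE)
  rownames(copies) <- variants$variant_id
  list(variants = variants, copies = copies)
}

#' Filter a genotype table to common SNVs
#'
#' @param genotypes genotype table.
#' @param min_af minimum allele frequency (default 0.05).
#' @return filtered genotype table with an audit attribute.
#' @export
filter_common_snvs <- function(genotypes, min_af = 0.05) {
  v <- genotypes$variants
  is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  common <- !is.na(v$allele_frequency) & v$allele_frequency >= min_af
  keep <- is_snv & common
  out <- list(variants = v[keep, , drop = FALSE],
              copies = genotypes$copies[keep, , drop = FALSE])
  attr(out, "audit") <- data.frame(
    rule = c("non_snv", "rare_allele"),
    dropped = c(sum(!is_snv), sum(is_snv & !common)))
  out
}

#' Serialise a scaled density (grid, point estimate, band) as TSV + JSON
#'
#' The TSV holds the per-grid-point values; a JSON sidecar records the
#' parameters (target PSI, bandwidth, bootstrap count, band level, seed)
#' for provenance.
#'
#' @param sd a `scaled_density` from [density_with_band()].
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scaled_density <- function(sd, path) {
  stopifnot(inherits(sd, "scaled_density"))
  utils::write.table(
    data.frame(grid = sd$grid, density = sd$density,
               band_lower = sd$band_lower, band_upper = sd$band_upper),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(target_psi = sd$target_psi, bw = sd$bw, n_boot = sd$n_boot,
         band_level = sd$band_level, seed = sd$seed,
         n_grid = length(sd$grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
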