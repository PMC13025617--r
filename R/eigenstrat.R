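#' Read a genotype dataset from EIGENSTRAT files
#'
#' Reads the `.geno`/`.snp`/`.ind` trio used by the ADMIXTOOLS family of
#' programs. Both the unpacked ASCII dialect (one digit per sample per line)
#' and the PACKEDANCESTRYMAP binary dialect (2 bits per call) are supported
#' and auto-detected. On disk each digit counts copies of the *reference*
#' allele (column 5 of the `.snp` file) with 9 for missing, the EIGENSTRAT
#' convention; in memory calls are stored as alternate-allele dosages with
#' `NA` for missing. Genetic positions (`.snp` column 3) are interpreted as
#' Morgans, the format standard.
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp` and
#'   `<prefix>.ind` must all exist.
#' @param pseudo_haploid Passed to [genotype_dataset()]; `NULL` auto-detects.
#' @return A [genotype_dataset()].
#' @export
read_eigenstrat <- function(prefix, pseudo_haploid = NULL) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing EIGENSTRAT file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  snp <- read_snp(paths[2])
  ind <- read_ind(paths[3])
  ref_counts <- read_geno(paths[1], n_variants = nrow(snp), n_samples = nrow(ind))
  calls <- 2L - ref_counts  # disk counts ref copies; internal = alt dosage
  genotype_dataset(snp, ind, calls, pseudo_haploid = pseudo_haploid)
}

#' Write a genotype dataset to EIGENSTRAT files
#'
#' @param ds A [genotype_dataset()].
#' @param prefix Output path prefix.
#' @param packed Write the PACKEDANCESTRYMAP binary `.geno` instead of ASCII.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(ds, prefix, packed = FALSE) {
  stopifnot(inherits(ds, "gt_dataset"))
  v <- ds$variants
  chrom_out <- ifelse(v$chrom == "X", "23", v$chrom)
  snp_lines <- sprintf("%s\t%s\t%.10g\t%d\t%s\t%s",
                       v$id, chrom_out, v$gpos, as.integer(v$pos), v$ref, v$alt)
  writeLines(snp_lines, paste0(prefix, ".snp"))
  s <- ds$samples
  writeLines(sprintf("%s\t%s\t%s", s$id, s$sex, s$population), paste0(prefix, ".ind"))
  ref_counts <- 2L - ds$calls
  ref_counts[is.na(ref_counts)] <- 9L
  if (packed) {
    write_geno_packed(ref_counts, paste0(prefix, ".geno"))
  } else {
    mode(ref_counts) <- "character"
    writeLines(apply(ref_counts, 1, paste0, collapse = ""), paste0(prefix, ".geno"))
  }
  invisible(prefix)
}

read_snp <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (ncol(raw) < 6) {
    stop(".snp file must have 6 columns (id chrom gpos pos ref alt): ", path,
         call. = FALSE)
  }
  tibble::tibble(
    id = raw[[1]], chrom = raw[[2]],
    gpos = as.numeric(raw[[3]]), pos = as.integer(raw[[4]]),
    ref = raw[[5]], alt = raw[[6]]
  )
}

read_ind <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3) stop(".ind file must have 3 columns: ", path, call. = FALSE)
  tibble::tibble(id = raw[[1]], sex = toupper(raw[[2]]), population = raw[[3]])
}

read_geno <- function(path, n_variants, n_samples) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4)
  close(con)
  if (rawToChar(magic) == "GENO") {
    read_geno_packed(path, n_variants, n_samples)
  } else {
    read_geno_ascii(path, n_variants, n_samples)
  }
}

read_geno_ascii <- function(path, n_variants, n_samples) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != n_variants) {
    stop(sprintf("%s has %d genotype lines but the .snp file lists %d variants",
                 path, length(lines), n_variants), call. = FALSE)
  }
  widths <- nchar(lines)
  if (any(widths != n_samples)) {
    bad <- which(widths != n_samples)[1]
    stop(sprintf("%s line %d has %d calls but the .ind file lists %d samples",
                 path, bad, widths[bad], n_samples), call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                  nrow = n_variants, byrow = TRUE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = n_variants), arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code '%s' at %s line %d",
                 chars[bad[1], bad[2]], path, bad[1]), call. = FALSE)
  }
  g <- matrix(as.integer(chars), nrow = n_variants)
  g[g == 9L] <- NA_integer_
  g
}

# PACKEDANCESTRYMAP: a header record then one record per SNP, 2 bits per
# sample (0/1/2 ref copies, 3 = missing), sample 1 in the high bits of byte 1.
# Record length is max(ceiling(n_samples / 4), 48) bytes.
packed_rlen <- function(n_samples) max(ceiling(n_samples / 4), 48L)

read_geno_packed <- function(path, n_variants, n_samples) {
  raw <- readBin(path, "raw", file.info(path)$size)
  header <- strsplit(trimws(rawToChar(raw[seq_len(min(48, length(raw)))])), "\\s+")[[1]]
  nind <- as.integer(header[2]); nsnp <- as.integer(header[3])
  if (!is.na(nind) && nind != n_samples) {
    stop(sprintf("packed .geno header says %d samples but .ind lists %d",
                 nind, n_samples), call. = FALSE)
  }
  rlen <- packed_rlen(n_samples)
  need <- rlen * (n_variants + 1L)
  if (length(raw) < need) {
    stop(sprintf("packed .geno too short for %d variants (%d bytes, need %d)",
                 n_variants, length(raw), need), call. = FALSE)
  }
  if (!is.na(nsnp) && nsnp != n_variants) {
    stop(sprintf("packed .geno header says %d variants but .snp lists %d",
                 nsnp, n_variants), call. = FALSE)
  }
  body <- raw[-seq_len(rlen)][seq_len(rlen * n_variants)]
  bytes <- matrix(as.integer(body), nrow = rlen)  # one column per SNP
  g <- matrix(NA_integer_, nrow = n_variants, ncol = n_samples)
  for (k in 0:3) {  # position of the sample within its byte
    idx <- seq(from = k + 1, by = 4, length.out = ceiling((n_samples - k) / 4))
    idx <- idx[idx <= n_samples]
    if (length(idx) == 0) next
    byte_row <- (idx - 1) %/% 4 + 1
    shift <- 2 * (3 - k)
    vals <- t(bytes[byte_row, , drop = FALSE] %/% 2^shift %% 4L)
    g[, idx] <- vals
  }
  g[g == 3L] <- NA_integer_
  g[is.na(g)] <- 9L
  mode(g) <- "integer"
  g[g == 9L] <- NA_integer_
  g
}

write_geno_packed <- function(ref_counts, path) {
  n_variants <- nrow(ref_counts); n_samples <- ncol(ref_counts)
  rlen <- packed_rlen(n_samples)
  g <- ref_counts
  g[g == 9L] <- 3L
  pad <- (-n_samples) %% 4
  if (pad > 0) g <- cbind(g, matrix(0L, n_variants, pad))
  # pack 4 samples per byte, first sample in the high bits
  bytes <- g[, seq(1, ncol(g), by = 4), drop = FALSE] * 64L +
    g[, seq(2, ncol(g), by = 4), drop = FALSE] * 16L +
    g[, seq(3, ncol(g), by = 4), drop = FALSE] * 4L +
    g[, seq(4, ncol(g), by = 4), drop = FALSE]
  records <- matrix(as.raw(0), nrow = rlen, ncol = n_variants)
  records[seq_len(ncol(bytes)), ] <- t(matrix(as.raw(bytes), ncol = ncol(bytes)))
  header <- sprintf("GENO %d %d %x %x", n_samples, n_variants,
                    text_hash(colnames(ref_counts)), text_hash(rownames(ref_counts)))
  hraw <- as.raw(rep(0, rlen))
  hbytes <- charToRaw(header)
  hraw[seq_along(hbytes)] <- hbytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hraw, con)
  writeBin(as.vector(records), con)
  invisible(path)
}

# FNV-1a style 31-bit hash of the id list; recorded in the packed header for
# provenance (readers do not depend on it).
text_hash <- function(ids) {
  if (is.null(ids)) return(0)
  h <- 2166136261 %% 2^31
  for (ch in utf8ToInt(paste(ids, collapse = ":"))) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2^31
  }
  h
}

#' Read a sample-to-population assignment table
#'
#' @param path TSV file with columns `sample_id` and `population` (header
#'   optional).
#' @return A tibble with columns `sample_id`, `population`.
#' @export
read_populations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample", tolower(first))
  raw <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  tibble::tibble(sample_id = raw[[1]], population = raw[[2]])
}

#' Import biallelic SNP genotypes from a VCF file
#'
#' Minimal convenience importer for small VCFs: biallelic SNPs only,
#' GT field only. Larger callsets should be converted to EIGENSTRAT upstream.
#'
#' @param path Path to an uncompressed VCF.
#' @param populations Optional tibble from [read_populations()]; samples
#'   without an assignment get population `"Unassigned"`.
#' @return A [genotype_dataset()].
#' @export
read_vcf_genotypes <- function(path, populations = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  sample_ids <- header[-(1:9)]
  fields <- do.call(rbind, body)
  keep <- nchar(fields[, 4]) == 1 & nchar(fields[, 5]) == 1 & fields[, 5] != "."
  fields <- fields[keep, , drop = FALSE]
  gt <- fields[, -(1:9), drop = FALSE]
  gt <- sub(":.*$", "", gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[gt %in% c("0/0", "0|0", "0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1", "1")] <- 2L
  variants <- tibble::tibble(
    id = ifelse(fields[, 3] == ".",
                paste0(fields[, 1], "_", fields[, 2]), fields[, 3]),
    chrom = fields[, 1], pos = as.integer(fields[, 2]),
    gpos = as.numeric(fields[, 2]) * 1e-8,  # 1 cM/Mb placeholder map
    ref = fields[, 4], alt = fields[, 5]
  )
  pop <- rep("Unassigned", length(sample_ids))
  if (!is.null(populations)) {
    m <- match(sample_ids, populations$sample_id)
    pop[!is.na(m)] <- populations$population[m[!is.na(m)]]
  }
  samples <- tibble::tibble(id = sample_ids, population = pop)
  genotype_dataset(variants, samples, dose, pseudo_haploid = FALSE)
}
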