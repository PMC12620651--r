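#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file into a [geno_matrix()] of alternate-allele dosages.
#' The `GT` field is used when present (the dosage is the count of ALT
#' alleles in the call, so tetraploid `0/0/1/1` gives 2); otherwise a
#' numeric `DS` dosage field is accepted. The ALT allele is always the
#' counted allele; cross-performance predictions are invariant to this
#' choice when effects are re-estimated under the same coding. Marker order
#' follows the file.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param ploidy Declared ploidy (2, 4 or 6); GT calls with a different
#'   number of alleles raise a ploidy-mismatch error.
#' @return A [geno_matrix()] with marker metadata (`chrom`, `pos`) attached.
#' @export
read_vcf <- function(path, ploidy = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      stop("malformed VCF '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  has_gt <- "GT" %in% unlist(strsplit(vcf@gt[, "FORMAT"], ":"))
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- gt_to_dosage(gt, ploidy)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    if (all(is.na(ds))) {
      stop("VCF '", path, "' has neither GT nor DS genotype fields",
           call. = FALSE)
    }
    dos <- matrix(suppressWarnings(as.numeric(ds)), nrow = nrow(ds),
                  dimnames = dimnames(ds))
    if (any(dos < 0 | dos > ploidy, na.rm = TRUE)) {
      stop("DS dosages outside [0, ", ploidy, "]", call. = FALSE)
    }
  }
  rownames(dos) <- ids
  map <- tibble::tibble(
    marker = ids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"])
  )
  geno_matrix(t(dos), ploidy, map)
}

# GT strings ("0/1", "0|1|1|0", "./.") -> ALT-allele counts; errors when the
# number of alleles in a call disagrees with the declared ploidy.
gt_to_dosage <- function(gt, ploidy) {
  u <- unique(as.vector(gt))
  u_clean <- u[!is.na(u)]
  vals <- vapply(u_clean, function(g) {
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    if (length(alleles) != ploidy) {
      stop("GT call '", g, "' has ", length(alleles),
           " alleles but declared ploidy is ", ploidy, call. = FALSE)
    }
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a)) stop("unparseable GT call '", g, "'", call. = FALSE)
    sum(a > 0)
  }, numeric(1))
  lookup <- c(stats::setNames(vals, u_clean))
  out <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  ok <- !is.na(gt)
  out[ok] <- lookup[gt[ok]]
  out
}

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read genotypes from a HapMap file
#'
#' Parses a tab-delimited HapMap file (the 11 standard metadata columns
#' followed by one column per sample) into a [geno_matrix()]. Calls may be
#' two-letter (`AA`, `AC`), slash-separated (`A/C`) or single IUPAC codes
#' (`M` for the A/C heterozygote). The counted allele is the second allele
#' listed in the `alleles` column, so dosages agree with the ALT-count
#' convention of [read_vcf()] when REF/ALT match the listed order. `N`/`NN`
#' and `--` are missing. Heterozygous calls at ploidy > 2 are rejected:
#' HapMap cannot express partial polyploid dosage unambiguously.
#'
#' @inheritParams read_vcf
#' @return A [geno_matrix()].
#' @export
read_hapmap <- function(path, ploidy = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  meta_cols <- 11L
  if (ncol(tab) <= meta_cols) {
    stop("HapMap file '", path,
         "' has no sample columns after the 11 metadata columns",
         call. = FALSE)
  }
  alleles <- strsplit(tab[[2]], "/")
  if (any(lengths(alleles) != 2)) {
    stop("non-biallelic `alleles` entries in HapMap file", call. = FALSE)
  }
  ref <- vapply(alleles, `[`, "", 1)
  alt <- vapply(alleles, `[`, "", 2)
  samples <- names(tab)[-seq_len(meta_cols)]
  m <- nrow(tab)
  dos <- matrix(NA_real_, nrow = length(samples), ncol = m,
                dimnames = list(samples, tab[[1]]))
  for (i in seq_len(m)) {
    calls <- toupper(as.character(tab[i, -seq_len(meta_cols)]))
    dos[, i] <- hapmap_call_dosage(calls, ref[i], alt[i], ploidy,
                                   marker = tab[[1]][i])
  }
  map <- tibble::tibble(marker = tab[[1]], chrom = tab[[3]],
                        pos = as.integer(tab[[4]]))
  geno_matrix(dos, ploidy, map)
}

hapmap_call_dosage <- function(calls, ref, alt, ploidy, marker) {
  out <- rep(NA_real_, length(calls))
  for (j in seq_along(calls)) {
    cl <- gsub("/", "", calls[j])
    if (cl %in% c("N", "NN", "--", "", "NA")) next
    if (nchar(cl) == 1) {
      if (cl %in% names(IUPAC_HET)) {
        pair <- sort(c(ref, alt))
        if (paste(pair, collapse = "") != IUPAC_HET[[cl]]) {
          stop("IUPAC code '", cl, "' at marker ", marker,
               " inconsistent with alleles ", ref, "/", alt, call. = FALSE)
        }
        if (ploidy > 2) {
          stop("heterozygous HapMap call at ploidy ", ploidy, " (marker ",
               marker, "): HapMap cannot encode partial polyploid dosage",
               call. = FALSE)
        }
        out[j] <- 1
      } else if (cl %in% c(ref, alt)) {
        # single-letter homozygote shorthand
        out[j] <- if (cl == alt) ploidy else 0
      } else {
        stop("unknown allele code '", calls[j], "' at marker ", marker,
             call. = FALSE)
      }
    } else {
      ch <- strsplit(cl, "")[[1]]
      if (!all(ch %in% c(ref, alt))) {
        stop("unknown allele code '", calls[j], "' at marker ", marker,
             call. = FALSE)
      }
      if (length(unique(ch)) > 1) {
        if (ploidy > 2) {
          stop("heterozygous HapMap call at ploidy ", ploidy, " (marker ",
               marker, "): HapMap cannot encode partial polyploid dosage",
               call. = FALSE)
        }
        out[j] <- sum(ch == alt)
      } else {
        out[j] <- if (ch[1] == alt) ploidy else 0
      }
    }
  }
  out
}
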