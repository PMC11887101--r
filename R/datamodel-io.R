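#' Read a samples-by-metabolites concentration table
#'
#' Reads a CSV whose header row names the metabolites and whose rows are
#' samples, into the tidy layout used throughout the package: a tibble with a
#' `sample_id` column, an optional `plate` column, and one numeric column per
#' metabolite (concentrations in uM). Empty cells become `NA`.
#'
#' @param path Path to a CSV file. The first column is taken as the sample
#'   identifier.
#' @param plate_column Optional name of a column holding the analytical plate
#'   (batch) label; it is renamed to `plate`.
#' @param pool_column Optional name of a logical column flagging quality
#'   control pool samples; renamed to `is_pool`.
#' @return A tibble with columns `sample_id`, optionally `plate` and
#'   `is_pool`, and one numeric column per metabolite.
#' @export
read_metabolite_csv <- function(path, plate_column = NULL, pool_column = NULL) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), ",", fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  if (anyDuplicated(hdr)) {
    abort(paste0("duplicated metabolite id(s): ",
                 toString(unique(hdr[duplicated(hdr)]))))
  }
  raw <- suppressMessages(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE))
  names(raw)[1] <- "sample_id"
  if (!is.null(plate_column)) {
    if (!plate_column %in% names(raw)) abort(paste0("plate column '", plate_column, "' not found"))
    names(raw)[names(raw) == plate_column] <- "plate"
  }
  if (!is.null(pool_column)) {
    if (!pool_column %in% names(raw)) abort(paste0("pool column '", pool_column, "' not found"))
    names(raw)[names(raw) == pool_column] <- "is_pool"
    raw$is_pool <- as.logical(raw$is_pool)
  }
  met_cols <- metabolite_ids(raw)
  if (anyDuplicated(met_cols)) {
    abort(paste0("duplicated metabolite id(s): ",
                 toString(unique(met_cols[duplicated(met_cols)]))))
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicated sample id(s): ",
                 toString(unique(raw$sample_id[duplicated(raw$sample_id)]))))
  }
  for (cc in met_cols) {
    v <- raw[[cc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad)) {
      abort(paste0("non-numeric value '", v[bad[1]], "' in column '", cc,
                   "', row ", bad[1]))
    }
    num[!is.na(num) & num < 0] <- num[!is.na(num) & num < 0] # keep; validated below
    raw[[cc]] <- num
  }
  vals <- as.matrix(raw[met_cols])
  if (any(vals < 0, na.rm = TRUE)) abort("negative concentrations are not allowed")
  as_tibble(raw)
}

#' Write a metabolite table to CSV
#'
#' Inverse of [read_metabolite_csv()]; values round-trip exactly (full double
#' precision).
#'
#' @param data Metabolite tibble (`sample_id` + metabolite columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Construct a genotype matrix object
#'
#' Bundles a samples-by-SNPs dosage matrix (0/1/2 copies of the minor allele,
#' `NA` allowed) with its SNP map. Alleles are polarized so that the dosage
#' counts the minor allele; columns already polarized are left untouched.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}. Row and column names are used as sample and SNP ids.
#' @param map Tibble with columns `snp_id`, `chromosome`, `position_bp`,
#'   optionally `allele_ref`, `allele_alt`. One row per dosage column.
#' @param polarize If `TRUE` (default), columns with allele frequency > 0.5
#'   are flipped (dosage 2 - d, ref/alt swapped).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix) and `map` (tibble, including a computed `maf` column).
#' @export
genotype_matrix <- function(dosages, map, polarize = TRUE) {
  dosages <- as.matrix(dosages)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  if (ncol(dosages) != nrow(map)) abort("map rows must match dosage columns")
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp_id
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  map <- as_tibble(map)
  if (!all(c("snp_id", "chromosome", "position_bp") %in% names(map))) {
    abort("map needs columns snp_id, chromosome, position_bp")
  }
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  if (polarize && any(af > 0.5)) {
    flip <- which(af > 0.5)
    dosages[, flip] <- 2 - dosages[, flip]
    if (all(c("allele_ref", "allele_alt") %in% names(map))) {
      tmp <- map$allele_ref[flip]
      map$allele_ref[flip] <- map$allele_alt[flip]
      map$allele_alt[flip] <- tmp
    }
    af[flip] <- 1 - af[flip]
  }
  map$maf <- unname(af)
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs on ", length(unique(x$map$chromosome)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from dosage text formats
#'
#' Supports a plain CSV of dosages (first column = sample id, remaining
#' columns = SNPs) paired with a SNP map CSV, and the PLINK `.raw` additive
#' coding export (six leading pedigree columns, then one `SNP_allele` column
#' per variant).
#'
#' @param path Path to the dosage file.
#' @param format `"csv_dosage"` or `"plink_raw"`.
#' @param map For `csv_dosage`, a tibble or CSV path with `snp_id`,
#'   `chromosome`, `position_bp`. For `plink_raw` a map is optional; a
#'   placeholder map (one chromosome, index positions) is built if absent.
#' @return A [genotype_matrix()] with minor-allele polarized dosages and
#'   per-SNP MAF (missing dosages ignored in the frequency).
#' @export
read_genotype_matrix <- function(path, format = c("csv_dosage", "plink_raw"),
                                 map = NULL) {
  format <- match.arg(format)
  if (format == "csv_dosage") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    ids <- raw[[1]]
    dos <- vapply(raw[-1], function(v) suppressWarnings(as.numeric(v)),
                  numeric(nrow(raw)))
    dos <- matrix(dos, nrow = nrow(raw), dimnames = list(ids, names(raw)[-1]))
    if (is.null(map)) abort("csv_dosage requires a SNP map")
    if (is.character(map)) map <- readr::read_csv(map, col_types = readr::cols(), progress = FALSE)
  } else {
    raw <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% names(raw))) abort("not a PLINK .raw file: missing pedigree columns")
    snp_cols <- setdiff(names(raw), lead)
    dos <- vapply(raw[snp_cols], function(v) suppressWarnings(as.numeric(v)),
                  numeric(nrow(raw)))
    dos <- matrix(dos, nrow = nrow(raw),
                  dimnames = list(raw$IID, sub("_[ACGT0-9]+$", "", snp_cols)))
    if (is.null(map)) {
      map <- tibble(snp_id = colnames(dos), chromosome = "1",
                    position_bp = seq_len(ncol(dos)))
    } else if (is.character(map)) {
      map <- readr::read_csv(map, col_types = readr::cols(), progress = FALSE)
    }
  }
  genotype_matrix(dos, map)
}

#' Write genotypes as a dosage CSV (with side-car map)
#'
#' @param geno A [genotype_matrix()].
#' @param path Output CSV for dosages; the map is written next to it with
#'   suffix `.map.csv`.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(geno, path) {
  df <- dplyr::bind_cols(tibble(sample_id = rownames(geno$dosages)),
                         as_tibble(geno$dosages))
  readr::write_csv(df, path, progress = FALSE)
  readr::write_csv(geno$map, paste0(path, ".map.csv"), progress = FALSE)
  invisible(path)
}

#' Read pedigree records
#'
#' Reads `individual,sire,dam` CSV records ("0" or empty field = unknown
#' parent), checks for duplicate individuals and ancestry cycles, and returns
#' the records topologically ordered (parents before offspring) with a
#' computed generation depth.
#'
#' @param path CSV path.
#' @return A tibble `id`, `sire`, `dam` (`NA` = unknown), `generation`
#'   (founders = 0), topologically sorted.
#' @export
read_pedigree <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1:3] <- c("id", "sire", "dam")
  ped_order(tibble(
    id = raw$id,
    sire = dplyr::na_if(dplyr::na_if(raw$sire, "0"), ""),
    dam = dplyr::na_if(dplyr::na_if(raw$dam, "0"), "")
  ))
}

# topological sort + generation depth; errors on duplicates and cycles
ped_order <- function(ped) {
  if (anyDuplicated(ped$id)) {
    abort(paste0("individual listed twice: ",
                 toString(unique(ped$id[duplicated(ped$id)]))))
  }
  n <- nrow(ped)
  gen <- rep(NA_integer_, n)
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  remaining <- seq_len(n)
  depth <- 0L
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      s <- sire_i[i]; d <- dam_i[i]
      (is.na(s) || !is.na(gen[s])) && (is.na(d) || !is.na(gen[d]))
    }, logical(1))]
    if (!length(ready)) {
      abort(paste0("pedigree cycle involving: ",
                   toString(utils::head(ped$id[remaining], 5))))
    }
    gen[ready] <- vapply(ready, function(i) {
      pg <- c(if (!is.na(sire_i[i])) gen[sire_i[i]],
              if (!is.na(dam_i[i])) gen[dam_i[i]])
      if (length(pg)) max(pg) + 1L else 0L
    }, integer(1))
    remaining <- setdiff(remaining, ready)
    depth <- depth + 1L
    if (depth > n + 1L) abort("pedigree cycle detected")
  }
  ped$generation <- gen
  dplyr::arrange(ped, .data$generation, match(.data$id, ped$id))
}

#' Read gene annotation from GFF3 or BED
#'
#' Keeps `gene` features only (GFF3) and converts BED's half-open 0-based
#' intervals to the 1-based inclusive coordinates used throughout the
#' package.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return Tibble `gene_id`, `chromosome`, `start_bp`, `end_bp`, `strand`,
#'   `name`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path, progress = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (format == "gff3") {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf != 9)) {
      abort(paste0("malformed GFF3 line ", body[which(nf != 9)[1]],
                   ": expected 9 tab-separated fields"))
    }
    f <- do.call(rbind, strsplit(lines[body], "\t", fixed = TRUE))
    keep <- f[, 3] == "gene"
    if (!any(keep)) {
      warn("no 'gene' features found; returning empty table")
      return(tibble(gene_id = character(), chromosome = character(),
                    start_bp = integer(), end_bp = integer(),
                    strand = character(), name = character()))
    }
    f <- f[keep, , drop = FALSE]
    attr_field <- f[, 9]
    pull_attr <- function(key) {
      m <- regmatches(attr_field, regexpr(paste0("(^|;)", key, "=[^;]*"), attr_field))
      out <- rep(NA_character_, length(attr_field))
      hit <- vapply(attr_field, function(a) grepl(paste0("(^|;)", key, "="), a), logical(1))
      out[hit] <- sub(paste0(".*", key, "="), "", m)
      out
    }
    gid <- pull_attr("ID")
    nm <- pull_attr("Name")
    tibble(
      gene_id = dplyr::coalesce(gid, nm, paste0("gene", seq_len(nrow(f)))),
      chromosome = f[, 1],
      start_bp = as.integer(f[, 4]),
      end_bp = as.integer(f[, 5]),
      strand = f[, 7],
      name = dplyr::coalesce(nm, gid)
    )
  } else {
    parts <- strsplit(trimws(lines[body]), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 3)) {
      abort(paste0("malformed BED line ", body[which(nf < 3)[1]],
                   ": fewer than 3 fields"))
    }
    f <- lapply(parts, function(p) c(p, rep(NA, 6 - length(p)))[1:6])
    f <- do.call(rbind, f)
    tibble(
      gene_id = dplyr::coalesce(f[, 4], paste0("gene", seq_len(nrow(f)))),
      chromosome = f[, 1],
      start_bp = as.integer(f[, 2]) + 1L,  # BED 0-based half-open -> 1-based inclusive
      end_bp = as.integer(f[, 3]),
      strand = dplyr::coalesce(f[, 6], "*"),
      name = dplyr::coalesce(f[, 4], NA_character_)
    )
  }
}

#' Write a result tibble as TSV with a provenance header
#'
#' All pipeline outputs use TSV with a commented header recording the package
#' version and, when given, the simulation seed.
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(data, path, seed = NULL) {
  hdr <- paste0("# metaboqtl ", as.character(utils::packageVersion("metaboqtl")),
                if (!is.null(seed)) paste0(" seed=", seed), " ", format(Sys.time(), "%Y-%m-%d"))
  readr::write_lines(hdr, path)
  readr::write_tsv(data, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
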