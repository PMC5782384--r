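# Cross container and R/qtl-style CSV input/output.
#
# Genotypes are stored as integer codes on a fixed internal alphabet:
#   1 = AA, 2 = AB, 3 = BB, 4 = not BB (AA or AB), 5 = not AA (AB or BB),
#   NA = missing, where allele A is the wild-founder allele and B the
# domestic-founder allele. Codes 4/5 represent partially informative
# markers, where one homozygote cannot be distinguished from the
# heterozygote.

GENO_CODES <- c("AA", "AB", "BB", "notBB", "notAA")

# Common genotype code conventions for R/qtl-style CSV files, in the order
# (AA, AB, BB, notBB, notAA). Auto-detection tries these in turn.
GENO_DIALECTS <- list(
  rqtl    = c("A", "H", "B", "D", "C"),
  verbose = c("AA", "AB", "BB", "notBB", "notAA"),
  numeric = c("1", "2", "3", "4", "5")
)

#' Construct a validated cross object
#'
#' Bundles a genetic map, a genotype matrix, phenotypes and covariates for an
#' intercross population into a single object, checking the shared-index and
#' map invariants used throughout the package.
#'
#' @param geno Integer matrix (individuals x markers) of genotype codes
#'   1 = AA, 2 = AB, 3 = BB, 4 = not-BB, 5 = not-AA, `NA` = missing, where
#'   A denotes the wild-founder allele. Column names must equal the marker
#'   names in `map`.
#' @param map Data frame with columns `marker`, `chr`, `pos_cm` and
#'   optionally `pos_mb` (physical position, 1-based Mb). Positions must be
#'   non-decreasing in cM within each chromosome; marker names unique.
#' @param pheno Data frame of numeric traits (one row per individual);
#'   missing values allowed.
#' @param covar Data frame of covariates; recognised columns are `sex`
#'   (levels `"male"`/`"female"`), `batch` and optionally `dye`. Sex and
#'   batch may not be missing for phenotyped individuals.
#'
#' @return An object of class `ail_cross`: a list with elements `geno`,
#'   `map`, `pheno`, `covar`.
#' @export
make_cross <- function(geno, map, pheno = NULL, covar = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  if (is.null(pheno)) pheno <- data.frame(row.names = seq_len(n))
  if (is.null(covar)) covar <- data.frame(row.names = seq_len(n))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("marker", "chr", "pos_cm") %in% names(map)))
    stop("map must have columns marker, chr, pos_cm")
  if (is.null(map$pos_mb)) map$pos_mb <- NA_real_
  map$chr <- as.character(map$chr)
  if (anyDuplicated(map$marker))
    stop("duplicate marker names in map: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  for (ch in unique(map$chr)) {
    p <- map$pos_cm[map$chr == ch]
    if (is.unsorted(p))
      stop("cM positions not non-decreasing on chromosome ", ch)
  }
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " columns but map has ", nrow(map), " markers")
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (!identical(colnames(geno), map$marker))
    stop("geno column names do not match map marker names")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 1L) || any(bad > 5L)))
    stop("genotype codes must be in 1..5 or NA")
  if (nrow(pheno) != n || nrow(covar) != n)
    stop("pheno and covar must have one row per individual")
  if (!is.null(covar$sex)) {
    covar$sex <- factor(as.character(covar$sex), levels = c("female", "male"))
    if (anyNA(covar$sex) && ncol(pheno) > 0 &&
        any(rowSums(!is.na(as.matrix(pheno))) > 0 & is.na(covar$sex)))
      stop("sex missing for phenotyped individuals")
  }
  if (!is.null(covar$batch)) covar$batch <- factor(as.character(covar$batch))
  if (!is.null(covar$dye)) covar$dye <- factor(as.character(covar$dye))
  structure(list(geno = geno, map = map, pheno = pheno, covar = covar),
            class = "ail_cross")
}

#' @export
print.ail_cross <- function(x, ...) {
  cat("ail_cross:", nrow(x$geno), "individuals,", nrow(x$map), "markers on",
      length(unique(x$map$chr)), "chromosomes\n")
  cat("  phenotypes:", paste(names(x$pheno), collapse = ", "), "\n")
  cat("  covariates:", paste(names(x$covar), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a cross
#' @param cross An `ail_cross` object.
#' @return Integer count.
#' @export
n_ind <- function(cross) nrow(cross$geno)

detect_geno_dialect <- function(values) {
  values <- setdiff(unique(values), c("", NA))
  for (nm in names(GENO_DIALECTS)) {
    if (all(values %in% GENO_DIALECTS[[nm]])) return(GENO_DIALECTS[[nm]])
  }
  stop("could not match genotype codes {",
       paste(values, collapse = ", "),
       "} to a known R/qtl-style convention; pass `genotypes` explicitly")
}

#' Read a cross from an R/qtl-style CSV file
#'
#' Parses the single-file comma-separated cross layout used by R/qtl: the
#' first row holds phenotype and marker names, the second row the chromosome
#' of each marker column (blank under phenotype columns), the third row the
#' map position in cM, and subsequent rows one individual each.
#'
#' Covariate columns named `sex`, `batch` and `dye` are split off into the
#' covariate table; remaining phenotype columns are taken as numeric traits.
#' A phenotype column `pos_mb` is not expected; physical marker positions can
#' be attached afterwards via the `map_mb` argument.
#'
#' @param path Path to the CSV file.
#' @param genotypes Character vector of length 5 giving the file's codes for
#'   (AA, AB, BB, not-BB, not-AA), or `NULL` (default) to auto-detect among
#'   common conventions such as `c("A","H","B","D","C")`.
#' @param na.strings Strings treated as missing genotype/phenotype values.
#' @param map_mb Optional data frame with columns `marker` and `pos_mb`
#'   giving physical positions to merge into the map.
#' @return An [make_cross()] `ail_cross` object.
#' @export
read_cross_csv <- function(path, genotypes = NULL, na.strings = c("-", "NA", ""),
                           map_mb = NULL) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (nrow(raw) < 3) stop("malformed cross CSV: fewer than 3 rows")
  header <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])
  pos_row <- as.character(raw[3, ])
  is_marker <- !(chr_row %in% c("", NA, " "))
  if (!any(is_marker)) stop("malformed cross CSV: no marker columns (empty chromosome row)")
  # marker columns must be contiguous at the right in this dialect
  first_marker <- which(is_marker)[1]
  if (any(!is_marker[seq(first_marker, length(is_marker))]))
    stop("malformed cross CSV: phenotype columns interleaved with marker columns")
  pos_cm <- suppressWarnings(as.numeric(pos_row[is_marker]))
  if (anyNA(pos_cm)) stop("malformed cross CSV: non-numeric map positions")
  map <- data.frame(marker = header[is_marker], chr = chr_row[is_marker],
                    pos_cm = pos_cm, stringsAsFactors = FALSE)
  data <- raw[-(1:3), , drop = FALSE]
  gtxt <- as.matrix(data[, is_marker, drop = FALSE])
  gtxt[gtxt %in% na.strings] <- NA
  if (is.null(genotypes)) genotypes <- detect_geno_dialect(gtxt)
  if (length(genotypes) < 3) stop("`genotypes` must give at least AA, AB, BB codes")
  geno <- matrix(match(gtxt, genotypes), nrow = nrow(gtxt))
  if (any(!is.na(gtxt) & is.na(geno)))
    stop("unrecognised genotype codes: ",
         paste(setdiff(unique(gtxt[!is.na(gtxt)]), genotypes), collapse = ", "))
  colnames(geno) <- map$marker
  ph_cols <- which(!is_marker)
  pheno <- data.frame(row.names = seq_len(nrow(data)))
  covar <- data.frame(row.names = seq_len(nrow(data)))
  for (j in ph_cols) {
    nmj <- header[j]
    v <- as.character(data[, j])
    v[v %in% na.strings] <- NA
    if (tolower(nmj) %in% c("sex", "batch", "dye")) {
      covar[[tolower(nmj)]] <- v
    } else if (tolower(nmj) %in% c("id", "individual")) {
      rownames(pheno) <- rownames(covar) <- v
      rownames(geno) <- v
    } else {
      pheno[[nmj]] <- suppressWarnings(as.numeric(v))
    }
  }
  if (!is.null(covar$sex)) {
    s <- tolower(covar$sex)
    s[s %in% c("m", "1", "male")] <- "male"
    s[s %in% c("f", "0", "female")] <- "female"
    covar$sex <- s
  }
  if (!is.null(map_mb)) {
    map$pos_mb <- map_mb$pos_mb[match(map$marker, map_mb$marker)]
  }
  make_cross(geno, map, pheno, covar)
}

#' Write a cross to an R/qtl-style CSV file
#'
#' Inverse of [read_cross_csv()]: phenotype and covariate columns first, then
#' marker columns with chromosome and cM rows, one individual per row.
#' Field order is fixed (covariates, then phenotypes alphabetically as
#' stored, then markers in map order), so output is byte-stable.
#'
#' @param cross An `ail_cross` object.
#' @param path Output file path.
#' @param genotypes Codes to write for (AA, AB, BB, not-BB, not-AA).
#' @param na Missing-value string.
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, genotypes = GENO_DIALECTS$rqtl, na = "-") {
  gtxt <- matrix(genotypes[cross$geno], nrow = nrow(cross$geno))
  gtxt[is.na(gtxt)] <- na
  left <- cbind(as.data.frame(lapply(cross$covar, as.character),
                              stringsAsFactors = FALSE, check.names = FALSE),
                as.data.frame(lapply(cross$pheno, function(v) {
                  out <- as.character(v); out[is.na(out)] <- na; out
                }), check.names = FALSE))
  n_left <- ncol(left)
  hdr <- c(names(left), cross$map$marker)
  row2 <- c(rep("", n_left), cross$map$chr)
  row3 <- c(rep("", n_left), format(cross$map$pos_cm, trim = TRUE, digits = 12))
  body <- cbind(as.matrix(left), gtxt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(paste(row2, collapse = ","), con)
  writeLines(paste(row3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Interpolate physical position from map position
#'
#' Piecewise-linear interpolation of Mb from cM between flanking markers that
#' carry both coordinates; outside the marker range, clamped extrapolation
#' with the terminal segment's slope, floored at 0 Mb.
#'
#' @param map Map data frame (`marker`, `chr`, `pos_cm`, `pos_mb`), e.g.
#'   `cross$map`.
#' @param chr Chromosome label.
#' @param pos_cm Numeric vector of query positions in cM.
#' @return Numeric vector of physical positions in Mb.
#' @export
cm_to_mb <- function(map, chr, pos_cm) {
  interp_coord(map, chr, pos_cm, from = "pos_cm", to = "pos_mb")
}

#' Interpolate map position from physical position
#'
#' @inheritParams cm_to_mb
#' @param pos_mb Numeric vector of query positions in Mb.
#' @return Numeric vector of map positions in cM.
#' @export
mb_to_cm <- function(map, chr, pos_mb) {
  interp_coord(map, chr, pos_mb, from = "pos_mb", to = "pos_cm")
}

interp_coord <- function(map, chr, x, from, to) {
  if (inherits(map, "ail_cross")) map <- map$map
  sub <- map[map$chr == as.character(chr) & !is.na(map[[from]]) & !is.na(map[[to]]), ]
  if (nrow(sub) == 0) stop("unknown chromosome or no dual-coordinate markers: ", chr)
  if (nrow(sub) < 2) stop("need >=2 markers with both coordinates on chromosome ", chr)
  sub <- sub[order(sub[[from]]), ]
  xs <- sub[[from]]; ys <- sub[[to]]
  out <- stats::approx(xs, ys, xout = pmin(pmax(x, min(xs)), max(xs)),
                       ties = mean)$y
  # clamped extrapolation with terminal slopes, floored at 0
  lo <- x < min(xs)
  if (any(lo)) {
    s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[lo] <- ys[1] + s * (x[lo] - xs[1])
  }
  hi <- x > max(xs)
  if (any(hi)) {
    k <- length(xs)
    s <- (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1])
    out[hi] <- ys[k] + s * (x[hi] - xs[k])
  }
  pmax(out, 0)
}

#' Derive growth traits from body-mass traits
#'
#' Growth is defined as the difference between consecutive body masses:
#' `g8.42 = w42 - w8`, `g42.112 = w112 - w42`, `g112.212 = w212 - w112`,
#' missing wherever either mass is missing. Early mass itself (hatch, day 8)
#' is confounded with maternal/egg effects, so only the differences are meant
#' to be scanned. Existing mass columns are left untouched.
#'
#' @param cross An `ail_cross` with some of the mass traits `w8`, `w42`,
#'   `w112`, `w212` (grams).
#' @return The cross with growth-trait columns added.
#' @export
derive_growth_traits <- function(cross) {
  ph <- cross$pheno
  pairs <- list(g8.42 = c("w8", "w42"), g42.112 = c("w42", "w112"),
                g112.212 = c("w112", "w212"))
  found <- FALSE
  for (g in names(pairs)) {
    a <- pairs[[g]][1]; b <- pairs[[g]][2]
    if (all(c(a, b) %in% names(ph))) {
      ph[[g]] <- ph[[b]] - ph[[a]]
      found <- TRUE
    }
  }
  if (!found) stop("no consecutive mass-trait pairs (w8/w42/w112/w212) found")
  cross$pheno <- ph
  cross
}
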