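#' Encode a subject's phenotype as a bounded numeric vector
#'
#' Age is normalized by dividing by 100 (clamped to 1 with a warning above
#' 100 years), sex is one-hot encoded over the fixed level order (F, M), and
#' the imaging site, when a level set is supplied, is one-hot encoded over
#' that order. Every element of the result lies in [0, 1].
#'
#' @param age age in years, in [0, 120]
#' @param sex "F" or "M"
#' @param site site level, or NA when no site is encoded
#' @param siteLevels ordered character vector of site levels;
#'   \code{character(0)} omits the site block entirely
#' @return numeric vector of length 1 + 2 + length(siteLevels)
#' @examples
#' encodePhenotype(50, "F")                      # c(0.5, 1, 0)
#' encodePhenotype(37, "M", "A", c("A","B","C")) # length 6, sum 2.37
#' @export
encodePhenotype <- function(age, sex, site = NA, siteLevels = character(0)) {
  if (!is.finite(age) || age < 0 || age > 120) {
    stop("age must be a finite value in [0, 120], got ", age)
  }
  if (age > 100) {
    warning("age ", age, " exceeds 100; clamping normalized age to 1.0")
    age <- 100
  }
  sex <- as.character(sex)
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M', got '", sex, "'")
  v <- c(age / 100, as.numeric(c("F", "M") == sex))
  if (length(siteLevels)) {
    site <- as.character(site)
    if (is.na(site) || !site %in% siteLevels) {
      stop("unknown site level '", site, "' (levels: ",
           paste(siteLevels, collapse = ", "), ")")
    }
    v <- c(v, as.numeric(siteLevels == site))
  }
  v
}

#' Phenotype encodings for a whole cohort
#'
#' @param cohort an \linkS4class{FCCohort}
#' @return numeric matrix, one column per subject, rows = encoding elements
#' @export
phenotypeMatrix <- function(cohort) {
  ph <- phenotypes(cohort)
  sl <- siteLevels(cohort)
  sapply(seq_len(nrow(ph)), function(i) {
    encodePhenotype(ph$age[i], ph$sex[i],
                    if (length(sl)) ph$site[i] else NA, sl)
  })
}

.MANIFEST_VERSION <- "1"

.writeMatrixText <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  }
}

.readMatrixText <- function(path, n) {
  v <- scan(path, what = double(), quiet = TRUE)
  if (length(v) != n * n) {
    stop("matrix file ", path, " has ", length(v),
         " values, expected ", n * n)
  }
  matrix(v, n, n, byrow = TRUE)
}

.writeMatrixBin <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
}

.readMatrixBin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = double(), n = n * n, size = 8L, endian = "little")
  if (length(v) != n * n) {
    stop("matrix file ", path, " truncated: ", length(v), " of ",
         n * n, " values")
  }
  matrix(v, n, n, byrow = TRUE)
}

#' Save a cohort to a directory
#'
#' Writes a versioned key/value manifest (\code{manifest.dcf}), the phenotype
#' CSV and one matrix file per subject (row-major, N rows by N columns),
#' either as delimited text for human inspection or as a raw little-endian
#' double container for bit-exact round-trips.
#'
#' @param cohort an \linkS4class{FCCohort}
#' @param outDir output directory (created if needed)
#' @param format "binary" (default, bit-exact) or "text"
#' @return path to the written manifest, invisibly usable by
#'   \code{\link{loadCohort}}
#' @export
saveCohort <- function(cohort, outDir, format = c("binary", "text")) {
  format <- match.arg(format)
  if (nSubjects(cohort) == 0L) stop("empty cohort: nothing to write")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  mdir <- file.path(outDir, "matrices")
  dir.create(mdir, showWarnings = FALSE)

  ph <- as.data.frame(phenotypes(cohort))
  ext <- if (format == "binary") "bin" else "txt"
  ph$matrix_file <- file.path("matrices",
                              paste0(ph$subject_id, ".", ext))
  utils::write.csv(ph, file.path(outDir, "phenotypes.csv"),
                   row.names = FALSE, quote = TRUE)

  mats <- fcMatrices(cohort)
  for (i in seq_len(nSubjects(cohort))) {
    p <- file.path(outDir, ph$matrix_file[i])
    if (format == "binary") .writeMatrixBin(mats[, , i], p)
    else .writeMatrixText(mats[, , i], p)
  }

  man <- matrix(c(
    .MANIFEST_VERSION,
    as.character(nRegions(cohort)),
    as.character(nSubjects(cohort)),
    format,
    "phenotypes.csv",
    paste(labelNames(cohort), collapse = ","),
    paste(siteLevels(cohort), collapse = ","),
    paste(cohort@regionIds, collapse = ","),
    cohort@provenance
  ), nrow = 1L)
  colnames(man) <- c("Version", "NRegions", "NSubjects", "Format",
                     "PhenotypeCSV", "LabelNames", "SiteLevels",
                     "RegionIds", "Provenance")
  manifest <- file.path(outDir, "manifest.dcf")
  write.dcf(man, manifest, width = 1e6)
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest written by \code{\link{saveCohort}}, loads the
#' phenotype CSV and every referenced matrix file, and validates all
#' \linkS4class{FCCohort} invariants (square, symmetric within 1e-6, entries
#' in [-1, 1], unit diagonal, uniform N across subjects).
#'
#' @param manifestPath path to \code{manifest.dcf} (or its directory)
#' @return a validated \linkS4class{FCCohort}
#' @export
loadCohort <- function(manifestPath) {
  if (dir.exists(manifestPath)) {
    manifestPath <- file.path(manifestPath, "manifest.dcf")
  }
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- read.dcf(manifestPath)
  root <- dirname(manifestPath)
  n <- as.integer(man[1, "NRegions"])
  format <- man[1, "Format"]
  ph <- utils::read.csv(file.path(root, man[1, "PhenotypeCSV"]),
                        stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  labelNames <- strsplit(man[1, "LabelNames"], ",", fixed = TRUE)[[1L]]
  sl <- man[1, "SiteLevels"]
  siteLevels <- if (nzchar(sl)) strsplit(sl, ",", fixed = TRUE)[[1L]]
                else character(0)
  regionIds <- strsplit(man[1, "RegionIds"], ",", fixed = TRUE)[[1L]]

  need <- c("subject_id", "age", "sex", "label", "matrix_file")
  miss <- setdiff(need, colnames(ph))
  if (length(miss)) {
    stop("phenotype CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(ph[intersect(colnames(ph),
                         c("subject_id", "age", "sex", "site", "label"))])) {
    stop("phenotype CSV contains missing values; imputation is not supported")
  }

  arr <- array(NA_real_, dim = c(n, n, nrow(ph)))
  for (i in seq_len(nrow(ph))) {
    p <- file.path(root, ph$matrix_file[i])
    if (!file.exists(p)) {
      stop("matrix file missing for subject ", ph$subject_id[i], ": ", p)
    }
    m <- tryCatch(
      if (format == "binary") .readMatrixBin(p, n) else .readMatrixText(p, n),
      error = function(e) {
        stop("subject ", ph$subject_id[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
    dev <- max(abs(m - t(m)))
    if (dev > .SYM_TOL) {
      stop("subject ", ph$subject_id[i], ": matrix asymmetric (max |x - t(x)| = ",
           format(dev, digits = 3), ")")
    }
    if (max(abs(m)) > 1 + 1e-12) {
      stop("subject ", ph$subject_id[i],
           ": correlation out of range [-1, 1] (max |x| = ",
           format(max(abs(m)), digits = 6), ")")
    }
    arr[, , i] <- m
  }
  ph$matrix_file <- NULL
  new("FCCohort", matrices = arr,
      phenotypes = S4Vectors::DataFrame(ph),
      regionIds = regionIds, labelNames = labelNames,
      siteLevels = siteLevels, provenance = man[1, "Provenance"])
}
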