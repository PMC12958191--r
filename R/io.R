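# Plain-text file formats of the BLUPF90 ecosystem: 3-column pedigree,
# "id + contiguous 012 string" SNP files (5 = missing), 2-column
# phenotype files, and the experiment report writer.

.split_fields <- function(lines) {
  strsplit(trimws(gsub(",", " ", lines)), "\\s+")
}

#' Read a 3-column pedigree file
#'
#' Columns animal, sire, dam (whitespace or comma separated; 0 =
#' unknown parent). A first line whose parent columns are non-numeric is
#' treated as a header and skipped. The pedigree is topologically
#' sorted so that parents precede offspring; cycles and self-parenting
#' are reported with the offending line.
#'
#' @param path File path.
#' @return An `apy_pedigree` with an `orig_line` attribute mapping
#'   animals back to input lines.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path, call. = FALSE)
  fields <- .split_fields(lines)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("line ", bad[1], ": expected 3 columns", call. = FALSE)
  first <- suppressWarnings(as.numeric(fields[[1]][2:3]))
  start <- if (anyNA(first)) 2L else 1L        # header detection
  fields <- fields[seq(start, length(fields))]
  line_no <- seq(start, length(lines))
  animal <- vapply(fields, `[`, "", 1)
  sire <- vapply(fields, `[`, "", 2)
  dam <- vapply(fields, `[`, "", 3)
  if (anyDuplicated(animal)) {
    i <- which(duplicated(animal))[1]
    stop("line ", line_no[i], ": duplicate animal ", animal[i], call. = FALSE)
  }
  self <- animal == sire | animal == dam
  if (any(self)) {
    i <- which(self)[1]
    stop("line ", line_no[i], ": animal ", animal[i], " is its own parent",
         call. = FALSE)
  }
  unknown <- "0"
  for (p in c(sire, dam)) {
    if (p != unknown && !(p %in% animal)) {
      stop("parent ", p, " has no pedigree line", call. = FALSE)
    }
  }
  # Kahn topological sort (detects cycles)
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  si <- ifelse(sire == unknown, NA_integer_, idx[sire])
  di <- ifelse(dam == unknown, NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)[1]
    stop("pedigree cycle involving animal ", animal[cyc],
         " (line ", line_no[cyc], ")", call. = FALSE)
  }
  df <- data.frame(animal = animal, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)[order, ]
  df$sire[df$sire == unknown] <- "0"
  # keep ids numeric when they are numeric, else keep as character
  num <- suppressWarnings(as.integer(df$animal))
  if (!anyNA(num)) {
    df$animal <- num
    df$sire <- as.integer(df$sire); df$dam <- as.integer(df$dam)
  } else {
    df$sire[df$sire == "0"] <- "0"; df$dam[df$dam == "0"] <- "0"
  }
  row.names(df) <- NULL
  ped <- new_pedigree(df)
  attr(ped, "orig_line") <- stats::setNames(line_no[order], animal[order])
  ped
}

#' Write a pedigree as 3-column text
#' @param pedigree An `apy_pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "apy_pedigree"))
  writeLines(paste(pedigree$animal, pedigree$sire, pedigree$dam), path)
  invisible(path)
}

#' Read a BLUPF90-style SNP file
#'
#' Each line holds an animal id, whitespace, and a contiguous genotype
#' string over {0,1,2,5}; all strings must have equal length. Code 5
#' (missing) is imputed to twice the observed allele frequency at the
#' locus (a real value); the number of imputed calls is reported with a
#' message.
#'
#' @param path File path.
#' @return A [genotype_set()] (entries possibly fractional after
#'   imputation).
#' @export
read_snp_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty SNP file: ", path, call. = FALSE)
  fields <- .split_fields(lines)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop("line ", bad[1], ": expected `id genotypes`", call. = FALSE)
  }
  ids <- vapply(fields, `[`, "", 1)
  gstr <- vapply(fields, `[`, "", 2)
  len <- nchar(gstr)
  if (length(unique(len)) != 1) {
    stop("ragged genotype strings (lengths ", paste(unique(len), collapse = ", "),
         ")", call. = FALSE)
  }
  chars <- strsplit(gstr, "")
  allowed <- c("0", "1", "2", "5")
  badchar <- vapply(chars, function(x) any(!x %in% allowed), logical(1))
  if (any(badchar)) {
    stop("line ", which(badchar)[1], ": genotype characters must be 0/1/2/5",
         call. = FALSE)
  }
  Z <- do.call(rbind, lapply(chars, as.numeric))
  miss <- Z == 5
  if (any(miss)) {
    Z[miss] <- NA
    locus_mean <- colMeans(Z, na.rm = TRUE)   # = 2 p-hat from observed calls
    if (anyNA(locus_mean)) {
      stop("locus ", which(is.na(locus_mean))[1], " has no observed genotypes",
           call. = FALSE)
    }
    for (j in which(colSums(miss) > 0)) Z[miss[, j], j] <- locus_mean[j]
    message(sum(miss), " missing genotype calls imputed to 2*p-hat")
  }
  num <- suppressWarnings(as.integer(ids))
  genotype_set(ids = if (!anyNA(num)) num else ids, Z = Z)
}

#' Write a genotype set as a BLUPF90-style SNP file
#'
#' Fractional (imputed) values are not representable; entries must be
#' integers 0/1/2.
#' @param genotypes A [genotype_set()].
#' @param path Output path.
#' @export
write_snp_file <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_set"))
  if (any(genotypes$Z != round(genotypes$Z))) {
    stop("genotype set contains non-integer (imputed) values", call. = FALSE)
  }
  gstr <- apply(genotypes$Z, 1, paste, collapse = "")
  writeLines(paste(genotypes$ids, gstr), path)
  invisible(path)
}

#' Read a 2-column phenotype file (animal id, value)
#' @param path File path.
#' @return Data frame with columns `animal`, `value`.
#' @export
read_phenotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- .split_fields(lines)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) stop("line ", bad[1], ": expected `id value`", call. = FALSE)
  ids <- vapply(fields, `[`, "", 1)
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  start <- 1L
  if (is.na(val[1]) && length(val) > 1) { start <- 2L }   # header
  ids <- ids[seq(start, length(ids))]; val <- val[seq(start, length(val))]
  if (anyNA(val)) stop("non-numeric phenotype value", call. = FALSE)
  num <- suppressWarnings(as.integer(ids))
  data.frame(animal = if (!anyNA(num)) num else ids, value = val)
}

#' Write phenotype records as whitespace-delimited text
#' @param phenotypes A `phenotype_set` or records data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  rec <- if (inherits(phenotypes, "phenotype_set")) phenotypes$records else phenotypes
  writeLines(paste(rec$animal, rec$value), path)
  invisible(path)
}

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}

.fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Write an experiment report to disk
#'
#' Produces human-readable TSV tables (2-decimal formatting, like the
#' published tables), a full-precision machine-readable JSON sidecar, a
#' metadata file (config echo, seeds, versions) and a short log. Files
#' are written atomically (temp-then-rename), so re-running with the
#' same configuration overwrites cleanly.
#'
#' @param report An [run_core_reduction_experiment()] report.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(output_dir)) {
      stop("cannot create output directory: ", output_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  fmt_stats <- function(df) {
    data.frame(scenario = df$scenario, group = as.character(df$group), n = df$n,
               correlation = .fmt2(df$correlation), intercept = .fmt2(df$intercept),
               slope = .fmt2(df$slope), MD = .fmt2(df$MD))
  }
  write_tsv <- function(df, name) {
    p <- file.path(output_dir, name)
    .atomic_write(function(tmp) utils::write.table(df, tmp, sep = "\t",
                                                   quote = FALSE, row.names = FALSE), p)
    paths <<- c(paths, p)
  }
  if (!is.null(report$stats_vs_benchmark)) {
    write_tsv(fmt_stats(report$stats_vs_benchmark), "comparison_stats.tsv")
  }
  if (!is.null(report$stats_vs_exact)) {
    write_tsv(fmt_stats(report$stats_vs_exact), "comparison_vs_exact.tsv")
  }
  if (!is.null(report$ratios)) {
    r <- report$ratios
    r$noncore_core_ratio <- sprintf("%.1f", r$noncore_core_ratio)
    write_tsv(r, "noncore_core_ratios.tsv")
  }
  if (!is.null(report$strata)) write_tsv(report$strata, "progeny_strata.tsv")
  meta <- list(
    package = "apycore",
    package_version = as.character(utils::packageVersion("apycore")),
    r_version = R.version.string,
    seeds = report$config$seeds,
    eigen_threshold = report$config$eigen_threshold,
    core_fractions = report$config$core_fractions,
    blend_alpha = report$config$blend_alpha,
    tau = report$config$tau, omega = report$config$omega,
    simulation = unclass(report$config$sim),
    sketch = if (is.null(report$config$sketch)) NULL else unclass(report$config$sketch),
    md_convention = "MD = mean(benchmark - candidate); regression: benchmark ~ candidate"
  )
  p <- file.path(output_dir, "run_metadata.json")
  .atomic_write(function(tmp) jsonlite::write_json(meta, tmp, auto_unbox = TRUE,
                                                   digits = NA, null = "null"), p)
  paths <- c(paths, p)
  sidecar <- list(stats_vs_benchmark = report$stats_vs_benchmark,
                  stats_vs_exact = report$stats_vs_exact,
                  fidelity = report$fidelity, ratios = report$ratios,
                  strata = report$strata, core_sizes = report$core_sizes)
  p <- file.path(output_dir, "report.json")
  .atomic_write(function(tmp) jsonlite::write_json(sidecar, tmp, dataframe = "columns",
                                                   digits = NA, null = "null"), p)
  paths <- c(paths, p)
  p <- file.path(output_dir, "run.log")
  .atomic_write(function(tmp) writeLines(c(
    paste("apycore experiment report written", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("replicates:", report$config$replicates,
          "failed:", if (is.null(report$failed)) 0 else nrow(report$failed)),
    paste("files:", paste(basename(paths), collapse = ", "))), tmp), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read the machine-readable report sidecar back
#' @param path Path to `report.json`.
#' @return List of data frames mirroring the report fields.
#' @export
read_report_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(el) if (is.list(el) && !is.data.frame(el)) as.data.frame(el) else el)
}
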