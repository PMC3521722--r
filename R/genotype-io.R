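#' Temporally structured microsatellite genotype data
#'
#' A `genotype_dataset` holds diploid microsatellite genotypes (allele sizes
#' in repeat units) for individuals partitioned into temporal samples, the
#' design used when the same vector population is re-sampled across years to
#' probe its demographic history. Missing calls are `NA`, never zero-coded.
#'
#' @param loci character vector of locus names.
#' @param samples list of [temporal_sample()] objects, in chronological file
#'   order.
#' @param genotypes list (one element per sample) of integer arrays with
#'   dimensions `c(n_individuals, n_loci, 2)`; allele sizes are positive
#'   integers, missing calls `NA` (both gene copies of a missing call are
#'   `NA`).
#' @return An object of class `genotype_dataset`.
#' @seealso [read_genepop()], [write_genepop()], [assign_generations()]
#' @export
genotype_dataset <- function(loci, samples, genotypes) {
  stopifnot(is.character(loci), length(loci) >= 1L,
            is.list(samples), is.list(genotypes),
            length(samples) == length(genotypes))
  for (i in seq_along(samples)) {
    g <- genotypes[[i]]
    if (!is.array(g) || length(dim(g)) != 3L || dim(g)[2] != length(loci) ||
        dim(g)[3] != 2L)
      stop("genotypes[[", i, "]] must be an n x n_loci x 2 array")
    if (any(!is.na(g) & g <= 0))
      stop("allele sizes must be positive integers")
    samples[[i]]$n_individuals <- dim(g)[1]
  }
  structure(list(loci = loci, samples = samples, genotypes = genotypes),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$loci), "loci,",
      length(x$samples), "temporal sample(s)\n")
  for (s in x$samples)
    cat(sprintf("  %-12s n=%-4d date=%s offset=%s\n", s$label, s$n_individuals,
                if (is.null(s$date)) "?" else format_ym(s$date),
                if (is.null(s$generation_offset)) "?" else s$generation_offset))
  invisible(x)
}

#' A single temporal sample
#'
#' @param label sample label.
#' @param date collection date with month resolution, either `"YYYY-MM"` or
#'   `list(year=, month=)`; may be `NULL` when only generation offsets are
#'   known.
#' @param generation_offset integer generations before the most recent sample
#'   (gbp); 0 for the most recent sample.
#' @export
temporal_sample <- function(label, date = NULL, generation_offset = NULL) {
  if (!is.null(date)) date <- parse_ym(date)
  if (!is.null(generation_offset) && generation_offset < 0)
    stop("generation_offset must be >= 0")
  structure(list(label = as.character(label), date = date,
                 n_individuals = NA_integer_,
                 generation_offset = generation_offset),
            class = "temporal_sample")
}

parse_ym <- function(x) {
  if (is.list(x)) {
    stopifnot(!is.null(x$year), !is.null(x$month))
    return(list(year = as.integer(x$year), month = as.integer(x$month)))
  }
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{1,2})$", as.character(x)))[[1]]
  if (length(m) != 3L) stop("date must be 'YYYY-MM': got ", x)
  list(year = as.integer(m[2]), month = as.integer(m[3]))
}

format_ym <- function(d) sprintf("%04d-%02d", d$year, d$month)

# fractional calendar years, month resolution
ym_frac <- function(d) d$year + (d$month - 1) / 12

#' Study-level configuration
#'
#' @param generations_per_year generations per calendar year used to convert
#'   calendar dates to coalescent generations. The default, 24, is the
#'   standard assumption for Afrotropical *Anopheles* populations with
#'   continuous year-round breeding.
#' @param intervention_start optional `"YYYY-MM"` date of the start of vector
#'   control, used only for annotation of outputs.
#' @param exclude_loci character vector of locus names dropped on import
#'   (e.g. loci failing null-allele screens upstream).
#' @export
study_config <- function(generations_per_year = 24, intervention_start = NULL,
                         exclude_loci = character()) {
  if (!(generations_per_year > 0)) stop("generations_per_year must be > 0")
  if (!is.null(intervention_start)) intervention_start <- parse_ym(intervention_start)
  structure(list(generations_per_year = generations_per_year,
                 intervention_start = intervention_start,
                 exclude_loci = exclude_loci),
            class = "study_config")
}

#' Read a GenePop file of temporally sampled genotypes
#'
#' Parses the GenePop dialect with 2- or 3-digit alleles; the digit width is
#' inferred from the first genotype encountered. Each `POP` block becomes one
#' temporal sample, in file order. All-zero codes (`00`, `000`) are missing
#' calls.
#'
#' @param path path to a GenePop text file.
#' @param sample_labels optional character vector of labels for the POP
#'   blocks; defaults to the identifier of each block's last individual (the
#'   GenePop convention) or `POP<i>`.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, sample_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("parse error at line 1: truncated GenePop file")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("parse error: no POP line found")
  # locus names: lines 2..first_pop-1, possibly comma-separated on one line
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("parse error at line 2: no locus names")

  pop_starts <- which(is_pop)
  digit <- NA_integer_
  samples <- list()
  genotypes <- list()
  for (b in seq_along(pop_starts)) {
    from <- pop_starts[b] + 1L
    to <- if (b < length(pop_starts)) pop_starts[b + 1] - 1L else length(lines)
    block <- if (to >= from) from:to else integer(0)
    block <- block[nzchar(trimws(lines[block]))]
    if (length(block) == 0L)
      stop("parse error at line ", pop_starts[b], ": empty POP block")
    mat <- array(NA_integer_, dim = c(length(block), length(loci), 2L))
    last_id <- ""
    for (r in seq_along(block)) {
      ln <- block[r]
      parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
      if (length(parts) < 2L)
        stop("parse error at line ", ln, ": expected 'id , genotypes'")
      last_id <- trimws(parts[1])
      toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != length(loci))
        stop("parse error at line ", ln, ": ", length(toks),
             " genotypes for ", length(loci), " loci")
      for (l in seq_along(toks)) {
        tk <- toks[l]
        if (!grepl("^[0-9]+$", tk) || !(nchar(tk) %in% c(4L, 6L)))
          stop("parse error at line ", ln, ": bad genotype '", tk, "'")
        w <- nchar(tk) / 2L
        if (is.na(digit)) digit <- w
        if (w != digit)
          stop("parse error at line ", ln,
               ": inconsistent allele digit width (", w, " vs ", digit, ")")
        a1 <- as.integer(substr(tk, 1L, w))
        a2 <- as.integer(substr(tk, w + 1L, 2L * w))
        if (a1 > 0L) mat[r, l, 1L] <- a1
        if (a2 > 0L) mat[r, l, 2L] <- a2
        # half-missing calls are treated as fully missing (diploid data)
        if (a1 == 0L || a2 == 0L) mat[r, l, ] <- NA_integer_
      }
    }
    lab <- if (!is.null(sample_labels)) sample_labels[b]
           else if (nzchar(last_id)) last_id else paste0("POP", b)
    samples[[b]] <- temporal_sample(lab)
    genotypes[[b]] <- mat
  }
  genotype_dataset(loci, samples, genotypes)
}

#' Write a genotype dataset as GenePop
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param title first header line.
#' @param digits allele digit width (2 or 3); default: 2 if all allele sizes
#'   fit in two digits, 3 otherwise.
#' @export
write_genepop <- function(dataset, path, title = "serialabc export",
                          digits = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(dataset$samples) == 0L ||
      sum(vapply(dataset$genotypes, function(g) dim(g)[1], 0L)) == 0L)
    stop("refusing to write an empty dataset")
  mx <- suppressWarnings(max(unlist(dataset$genotypes), na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  if (is.null(digits)) digits <- if (mx > 99L) 3L else 2L
  if (mx > 10^digits - 1)
    stop("allele size ", mx, " exceeds ", digits, "-digit width")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$loci, con)
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  for (i in seq_along(dataset$samples)) {
    writeLines("POP", con)
    g <- dataset$genotypes[[i]]
    for (r in seq_len(dim(g)[1])) {
      codes <- vapply(seq_along(dataset$loci), function(l) {
        a <- g[r, l, ]
        if (anyNA(a)) sprintf(fmt, 0L, 0L) else sprintf(fmt, a[1], a[2])
      }, "")
      writeLines(paste0(dataset$samples[[i]]$label, "_", r, " , ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Attach collection dates to the temporal samples
#'
#' @param dataset a [genotype_dataset()].
#' @param dates character vector (`"YYYY-MM"`) or list of dates, one per
#'   temporal sample, in dataset order.
#' @export
set_sample_dates <- function(dataset, dates) {
  stopifnot(length(dates) == length(dataset$samples))
  for (i in seq_along(dataset$samples))
    dataset$samples[[i]]$date <- parse_ym(dates[[i]])
  dataset
}

#' Convert calendar dates to generation offsets
#'
#' Each temporal sample gets `generation_offset = round(g_per_year * years
#' between its date and the most recent sample's date)`; the most recent
#' sample has offset 0. Dates carry month resolution, so offsets are computed
#' on fractional years and rounded to the nearest integer generation.
#'
#' @param dataset a [genotype_dataset()] whose samples carry dates.
#' @param config a [study_config()]; its `generations_per_year` (default 24)
#'   sets the calendar-to-generation conversion.
#' @return the dataset with `generation_offset` filled in on every sample.
#' @export
assign_generations <- function(dataset, config = study_config()) {
  fr <- vapply(dataset$samples, function(s) {
    if (is.null(s$date)) stop("sample '", s$label, "' has no collection date")
    ym_frac(s$date)
  }, 0)
  latest <- max(fr)
  for (i in seq_along(dataset$samples))
    dataset$samples[[i]]$generation_offset <-
      as.integer(round(config$generations_per_year * (latest - fr[i])))
  dataset
}

#' Generation offsets of the temporal samples
#' @param dataset a [genotype_dataset()].
#' @return integer vector in dataset sample order.
#' @export
generation_offsets <- function(dataset) {
  vapply(dataset$samples, function(s) {
    if (is.null(s$generation_offset)) NA_integer_
    else as.integer(s$generation_offset)
  }, 0L)
}

#' Drop loci by name
#' @param dataset a [genotype_dataset()].
#' @param loci character vector of locus names to remove.
#' @export
drop_loci <- function(dataset, loci) {
  keep <- !(dataset$loci %in% loci)
  if (all(keep)) return(dataset)
  dataset$genotypes <- lapply(dataset$genotypes,
                              function(g) g[, keep, , drop = FALSE])
  dataset$loci <- dataset$loci[keep]
  dataset
}
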