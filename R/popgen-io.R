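# Genotype container and GENEPOP input/output.

#' Diploid genotype matrix
#'
#' Container for co-dominant diploid genotypes: an `n_individuals x n_loci x 2`
#' integer array of allele codes (positive integers; `NA` for missing, with
#' both alleles of a call missing together), plus individual IDs and
#' population labels. Individual IDs are shared with the necrosis panel so
#' genetic and phenotypic data join on `colony_id`.
#'
#' @param calls integer array of dimension `c(n_individuals, n_loci, 2)`.
#' @param ids character vector of individual IDs.
#' @param populations character/factor vector of population labels.
#' @param loci character vector of locus names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ids, populations, loci) {
  stopifnot(length(dim(calls)) == 3L, dim(calls)[3] == 2L,
            dim(calls)[1] == length(ids), dim(calls)[2] == length(loci),
            length(populations) == length(ids))
  if (any(calls <= 0, na.rm = TRUE) || any(calls != round(calls), na.rm = TRUE)) {
    stop("allele codes must be positive integers", call. = FALSE)
  }
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half)) {
    stop("half-missing calls found: both alleles of a call must be missing together",
         call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(ids, loci, c("a1", "a2"))
  structure(list(calls = calls, ids = as.character(ids),
                 populations = as.character(populations),
                 loci = as.character(loci)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d populations (%s)\n",
              length(x$ids), length(x$loci), length(unique(x$populations)),
              paste(unique(x$populations), collapse = ", ")))
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP text format: a title line, one locus name per
#' line (or a single comma-separated line), then `POP`-delimited population
#' blocks of `id , gg gg ...` lines with 2- or 3-digit diploid allele coding
#' (missing coded as 00/000). Populations are labelled `pop1`, `pop2`, ... in
#' file order. Malformed headers, ragged locus counts and mixed digit widths
#' raise errors naming the offending line.
#'
#' @param path path to a GENEPOP file.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("malformed GENEPOP file: too few lines", call. = FALSE)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("malformed GENEPOP header: no POP line after the locus list", call. = FALSE)
  }
  loci <- trimws(lines[2:(first_pop - 1L)])
  loci <- loci[nzchar(loci)]
  if (length(loci) == 1L && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  if (length(loci) == 0L) stop("malformed GENEPOP header: no locus names", call. = FALSE)

  ids <- character(0); pops <- character(0); geno <- list()
  pop_idx <- 0L
  digit_width <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    raw <- lines[ln]
    if (!nzchar(trimws(raw))) next
    if (toupper(trimws(raw)) == "POP") { pop_idx <- pop_idx + 1L; next }
    if (pop_idx == 0L) stop(sprintf("line %d: individual before first POP", ln), call. = FALSE)
    parts <- strsplit(raw, ",")[[1]]
    if (length(parts) < 2L) {
      stop(sprintf("line %d: missing `,` separator between id and genotypes", ln),
           call. = FALSE)
    }
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(toks) != length(loci)) {
      stop(sprintf("line %d: %d genotype fields for %d loci", ln,
                   length(toks), length(loci)), call. = FALSE)
    }
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)) || any(grepl("[^0-9]", toks))) {
      stop(sprintf("line %d: genotypes must be uniform 4- or 6-digit numeric codes", ln),
           call. = FALSE)
    }
    w <- w / 2L
    if (is.na(digit_width)) digit_width <- w
    if (w != digit_width) {
      stop(sprintf("line %d: mixed allele digit widths (%d vs %d)", ln, w, digit_width),
           call. = FALSE)
    }
    a1 <- as.integer(substr(toks, 1L, digit_width))
    a2 <- as.integer(substr(toks, digit_width + 1L, 2L * digit_width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    bad <- xor(is.na(a1), is.na(a2))
    if (any(bad)) {
      stop(sprintf("line %d: half-missing call at locus %s", ln,
                   loci[which(bad)[1]]), call. = FALSE)
    }
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", pop_idx))
    geno[[length(geno) + 1L]] <- cbind(a1, a2)
  }
  if (length(ids) == 0L) stop("no individuals found", call. = FALSE)
  calls <- array(NA_integer_, dim = c(length(ids), length(loci), 2L))
  for (i in seq_along(ids)) calls[i, , ] <- geno[[i]]
  gm <- genotype_matrix(calls, ids = ids, populations = pops, loci = loci)
  attr(gm, "digit_width") <- digit_width
  gm
}

#' Write a GENEPOP genotype file
#'
#' Inverse of [read_genepop()]: writing then re-reading preserves allele
#' content, locus order and population structure.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @param digits allele digit width (2 or 3); default 2, or 3 automatically
#'   when any allele code exceeds 99.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, title = "heatgarden genotypes", digits = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mx <- suppressWarnings(max(gm$calls, na.rm = TRUE))
  digits <- digits %||% if (is.finite(mx) && mx > 99L) 3L else 2L
  if (!(digits %in% c(2L, 3L))) stop("digits must be 2 or 3", call. = FALSE)
  if (is.finite(mx) && mx >= 10^digits) {
    stop("allele codes too large for the requested digit width", call. = FALSE)
  }
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  lines <- c(title, gm$loci)
  for (p in unique(gm$populations)) {
    lines <- c(lines, "POP")
    for (i in which(gm$populations == p)) {
      a1 <- gm$calls[i, , 1]; a2 <- gm$calls[i, , 2]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      lines <- c(lines, paste0(gm$ids[i], " ,  ",
                               paste(sprintf(fmt, a1, a2), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
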