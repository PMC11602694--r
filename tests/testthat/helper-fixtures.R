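# Shared fixtures, all built in code.

# minimal panel: one row per colony x year x day from a value matrix
# vals: list of lists keyed [[colony]][[year]] -> numeric vector over days
toy_panel <- function(vals, days, population = "popA") {
  rows <- list()
  for (cid in names(vals)) {
    for (yr in names(vals[[cid]])) {
      v <- vals[[cid]][[yr]]
      rows[[length(rows) + 1L]] <- data.frame(
        colony_id = cid, population = population, year = as.integer(yr),
        day = days, necrosis_pct = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small genotype matrix from a list of per-individual allele-pair matrices
toy_genotypes <- function(calls_list, populations, loci = NULL) {
  n <- length(calls_list)
  L <- nrow(calls_list[[1]])
  loci <- loci %||% sprintf("loc%02d", seq_len(L))
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) calls[i, , ] <- calls_list[[i]]
  genotype_matrix(calls, ids = sprintf("ind%02d", seq_len(n)),
                  populations = populations, loci = loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# plain scores data frame for the gxe stage
toy_scores <- function(mat, years = colnames(mat)) {
  df <- expand.grid(colony_id = rownames(mat), year = years,
                    stringsAsFactors = FALSE)
  df$pc1 <- as.numeric(mat[cbind(df$colony_id, df$year)])
  df
}
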