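#' Construct an ecology table
#'
#' Per-taxon ecological codings: a 7-level habitat-use category, a primary
#' diet category (a prey category or `"generalist"`), optional per-taxon diet
#' proportions over the prey categories, and an optional count of dietary
#' records backing the proportions.
#'
#' @param taxa character vector of taxon names.
#' @param habitat character/factor, values from [habitat_levels()].
#' @param primary_diet character/factor; prey categories plus `"generalist"`.
#' @param diet_proportions optional numeric matrix (taxa x prey categories);
#'   each non-NA row must sum to 1 within 1e-9 with entries in \[0, 1\].
#' @param n_diet_records optional nonnegative integer per taxon.
#' @param categories prey-category set (default [diet_categories()]).
#' @return A data frame of class `ecology_table` with columns `taxon`,
#'   `habitat`, `primary_diet`, optionally `n_diet_records` and
#'   `prop_<category>` columns.
#' @export
ecology_table <- function(taxa, habitat, primary_diet,
                          diet_proportions = NULL, n_diet_records = NULL,
                          categories = diet_categories()) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop_validation("duplicate taxa in ecology table")
  habitat <- as.character(habitat)
  bad <- setdiff(unique(habitat[!is.na(habitat)]), habitat_levels())
  if (length(bad))
    stop_validation("unknown habitat value(s): %s", paste(bad, collapse = ", "))
  df <- data.frame(taxon = taxa,
                   habitat = factor(habitat, levels = habitat_levels()),
                   primary_diet = factor(as.character(primary_diet)),
                   stringsAsFactors = FALSE)
  if (!is.null(n_diet_records)) {
    if (any(n_diet_records < 0, na.rm = TRUE))
      stop_validation("n_diet_records must be nonnegative")
    df$n_diet_records <- as.integer(n_diet_records)
  }
  if (!is.null(diet_proportions)) {
    dp <- as.matrix(diet_proportions)
    if (is.null(colnames(dp))) colnames(dp) <- categories[seq_len(ncol(dp))]
    present <- !apply(is.na(dp), 1, any)
    if (any(dp[present, ] < -1e-12) || any(dp[present, ] > 1 + 1e-12))
      stop_validation("diet proportions must lie in [0, 1]")
    sums <- rowSums(dp[present, , drop = FALSE])
    if (any(abs(sums - 1) > 1e-9))
      stop_validation("diet proportions for taxon '%s' sum to %.12g, not 1",
                      taxa[present][which(abs(sums - 1) > 1e-9)[1]],
                      sums[which(abs(sums - 1) > 1e-9)[1]])
    colnames(dp) <- paste0("prop_", colnames(dp))
    df <- cbind(df, as.data.frame(dp, row.names = FALSE))
  }
  rownames(df) <- NULL
  attr(df, "categories") <- categories
  class(df) <- c("ecology_table", "data.frame")
  df
}

#' Extract the diet-proportion matrix from an ecology table
#' @param eco an `ecology_table`.
#' @param drop_na drop taxa with missing proportions (default TRUE).
#' @return numeric matrix (taxa x categories) with taxon rownames, or NULL if
#'   the table carries no proportion columns.
#' @export
diet_proportion_matrix <- function(eco, drop_na = TRUE) {
  pc <- grep("^prop_", names(eco), value = TRUE)
  if (!length(pc)) return(NULL)
  m <- as.matrix(eco[, pc, drop = FALSE])
  colnames(m) <- sub("^prop_", "", pc)
  rownames(m) <- eco$taxon
  if (drop_na) m <- m[!apply(is.na(m), 1, any), , drop = FALSE]
  m
}

#' Assign a primary diet category from diet proportions
#'
#' The primary diet is the prey category accounting for strictly more than
#' 50% of the diet; if no category exceeds 50% (including exact ties at 0.5)
#' the species is coded `"generalist"`.
#'
#' @param proportions named numeric vector over prey categories; must be
#'   nonnegative and sum to 1 (tolerance 1e-9).
#' @return a single category name or `"generalist"`.
#' @export
assign_primary_diet <- function(proportions) {
  if (any(proportions < 0))
    stop_validation("negative diet proportion")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_validation("diet proportions sum to %.12g, not 1", sum(proportions))
  i <- which.max(proportions)
  if (proportions[i] > 0.5) names(proportions)[i] %||% as.character(i)
  else "generalist"
}

#' Retain taxa with sufficiently many dietary records
#'
#' Keeps taxa whose record count is strictly greater than `min_records`
#' (default 10), i.e. the quantitative-diet subset used for
#' proportion-based analyses.
#'
#' @param eco an `ecology_table` with an `n_diet_records` column.
#' @param min_records strict lower bound on record count (default 10).
#' @return the filtered `ecology_table` (possibly zero rows).
#' @export
filter_quantitative_diet <- function(eco, min_records = 10) {
  if (is.null(eco$n_diet_records))
    stop_validation("ecology table has no n_diet_records column")
  keep <- !is.na(eco$n_diet_records) & eco$n_diet_records > min_records
  out <- eco[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the ecology CSV
#'
#' Header: `taxon,habitat,primary_diet[,n_diet_records][,prop_<category>...]`.
#'
#' @param path file path.
#' @return [read_ecology_csv()] returns an `ecology_table`;
#'   [write_ecology_csv()] returns `path` invisibly.
#' @export
read_ecology_csv <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pc <- grep("^prop_", names(df), value = TRUE)
  dp <- if (length(pc)) {
    m <- as.matrix(df[, pc, drop = FALSE]); colnames(m) <- sub("^prop_", "", pc)
    m
  } else NULL
  ecology_table(df$taxon, df$habitat, df$primary_diet,
                diet_proportions = dp,
                n_diet_records = df$n_diet_records,
                categories = if (length(pc)) sub("^prop_", "", pc)
                             else diet_categories())
}

#' @rdname read_ecology_csv
#' @param eco an `ecology_table`.
#' @export
write_ecology_csv <- function(eco, path) {
  out <- as.data.frame(eco)
  out$habitat <- as.character(out$habitat)
  out$primary_diet <- as.character(out$primary_diet)
  pc <- grep("^prop_", names(out), value = TRUE)
  for (col in pc) out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                                       scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
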