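# PPI cross-referencing: read curated PPI edge tables (HIPPIE v2.3 dialect
# or generic TSV), filter stromal-cluster DE genes (adjusted p < alpha in
# some cluster AND expressed in >= 10% of cells in some cluster), classify
# edges as B-BMSC / B-B / self-ligand, and detect condition-exclusive
# clusters.

#' Read a protein-protein interaction edge table
#'
#' Supports the HIPPIE v2.3 native tab format (UniProt-style identifiers
#' such as `BTK_HUMAN` in columns 1 and 3, confidence score in column 5)
#' and a generic three-column TSV (`gene_a`, `gene_b`, `confidence`).
#' Symbols are uppercased; duplicate unordered pairs are collapsed keeping
#' the maximal confidence; self-edges are preserved; edges below
#' `min_confidence` are dropped. Rows whose symbol cannot be resolved are
#' skipped with a reported count.
#'
#' @param path Input file.
#' @param dialect `"generic_tsv"` (default) or `"hippie_v23"`.
#' @param min_confidence Minimal confidence kept, in \[0, 1\].
#' @return Data frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
read_ppi_table <- function(path, dialect = c("generic_tsv", "hippie_v23"),
                           min_confidence = 0) {
  dialect <- match.arg(dialect)
  if (dialect == "generic_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "confidence")
    if (!all(need %in% names(df)))
      stop(sprintf("generic PPI TSV must have columns %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    df <- df[, need]
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 5L)
    if (length(bad) > 0)
      stop(sprintf("malformed HIPPIE row %d: fewer than 5 fields", bad[1]),
           call. = FALSE)
    sym <- function(id) sub("_HUMAN$", "", id)
    ga <- vapply(parts, function(p) sym(p[1]), character(1))
    gb <- vapply(parts, function(p) sym(p[3]), character(1))
    conf <- suppressWarnings(
      vapply(parts, function(p) as.numeric(p[5]), numeric(1)))
    unresolved <- ga == "" | gb == "" | ga == "-" | gb == "-" | is.na(conf)
    if (any(unresolved))
      message(sprintf("read_ppi_table: skipped %d row(s) with unresolvable symbols",
                      sum(unresolved)))
    df <- data.frame(gene_a = ga[!unresolved], gene_b = gb[!unresolved],
                     confidence = conf[!unresolved], stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0 && any(is.na(df$confidence)))
    stop("malformed PPI table: missing confidence values", call. = FALSE)
  df$gene_a <- toupper(df$gene_a)
  df$gene_b <- toupper(df$gene_b)
  # canonical unordered orientation, collapse duplicates keeping max conf
  swap <- df$gene_b < df$gene_a
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[df$confidence >= min_confidence, , drop = FALSE]
  if (nrow(df) > 0) {
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    ord <- order(key, -df$confidence)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read the B-cell core-vs-periphery DE table
#'
#' @param path TSV with columns `gene`, `direction`
#'   (`core_up`/`periphery_up`), `lfc`, `adj_p`.
#' @return Validated data frame (symbols uppercased).
#' @export
read_b_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "direction", "lfc", "adj_p")
  if (!all(need %in% names(df)))
    stop(sprintf("B DE table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  stopifnot(all(df$direction %in% c("core_up", "periphery_up")),
            all(df$adj_p >= 0 & df$adj_p <= 1))
  df$gene <- toupper(df$gene)
  if (anyDuplicated(df$gene))
    stop("duplicate genes in B DE table", call. = FALSE)
  df
}

#' Read the stromal-cluster DE table
#'
#' @param path TSV with columns `gene`, `cluster`, `pct_expressing`, `lfc`,
#'   `adj_p`.
#' @return Validated data frame (symbols uppercased).
#' @export
read_cluster_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "cluster", "pct_expressing", "lfc", "adj_p")
  if (!all(need %in% names(df)))
    stop(sprintf("cluster DE table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  stopifnot(all(df$pct_expressing >= 0 & df$pct_expressing <= 1),
            all(df$adj_p >= 0 & df$adj_p <= 1))
  df$gene <- toupper(df$gene)
  if (anyDuplicated(paste(df$gene, df$cluster)))
    stop("duplicate (gene, cluster) rows in cluster DE table", call. = FALSE)
  df
}

#' Stromal genes qualifying for crosstalk inference
#'
#' A gene qualifies iff it is differentially expressed (adjusted p < alpha)
#' in at least one cluster contrast AND expressed in at least `min_pct` of
#' cells in at least one cluster (both bounds as stated: `<` for alpha,
#' `>=` for pct). The returned map lists, per qualifying gene, the clusters
#' where its expressing fraction reaches `min_pct`.
#'
#' @param table Cluster DE table (see [read_cluster_de_table()]).
#' @param min_pct Minimal expressing-cell fraction (default 0.10).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Named list: gene -> integer vector of qualifying cluster ids.
#' @export
filter_bmsc_genes <- function(table, min_pct = 0.10, alpha = 0.05) {
  if (nrow(table) == 0L) return(stats::setNames(list(), character(0)))
  sp <- split(table, table$gene)
  out <- lapply(sp, function(g) {
    if (any(g$adj_p < alpha) && any(g$pct_expressing >= min_pct))
      sort(unique(g$cluster[g$pct_expressing >= min_pct]))
    else NULL
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Cross-reference PPI edges against DE gene sets
#'
#' Each PPI edge is kept and classified when its partners match the
#' differential-expression evidence: `B_BMSC` when one partner is in the
#' B-cell core-vs-periphery DE set and the other in the qualifying stromal
#' map; `B_B` when both partners are B-DE (core/periphery communication);
#' `self_ligand` for self-edges whose gene qualifies on either side. A gene
#' present in both sets produces records for both orientations, flagged
#' `dual`. Unmatched edges are dropped. Output order is deterministic
#' (class, then gene pair).
#'
#' @param ppi PPI edge table (`gene_a`, `gene_b`, `confidence`).
#' @param b_de B-cell DE table (`gene`, `direction`, `lfc`, `adj_p`); only
#'   rows with `adj_p < alpha` count as DE.
#' @param bmsc_map Qualifying-gene map from [filter_bmsc_genes()].
#' @param alpha Adjusted-p cutoff for the B DE set.
#' @param classes Edge classes to emit (subset of `B_BMSC`, `B_B`,
#'   `self_ligand`); restrict to `"B_BMSC"` for the strict Methods-only
#'   reading.
#' @return Data frame of interaction records: `gene_a`, `gene_b`, `class`,
#'   `b_gene`, `b_direction`, `bmsc_gene`, `bmsc_clusters`
#'   (comma-separated), `dual`, `confidence`.
#' @export
cross_reference <- function(ppi, b_de, bmsc_map, alpha = 0.05,
                            classes = c("B_BMSC", "B_B", "self_ligand")) {
  classes <- match.arg(classes, several.ok = TRUE)
  de <- b_de[b_de$adj_p < alpha, , drop = FALSE]
  b_set <- stats::setNames(de$direction, de$gene)
  bmsc_genes <- names(bmsc_map)
  rec <- list()
  emit <- function(...) rec[[length(rec) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ppi))) {
    ga <- ppi$gene_a[i]
    gb <- ppi$gene_b[i]
    conf <- ppi$confidence[i]
    a_b <- ga %in% names(b_set)
    b_b <- gb %in% names(b_set)
    a_m <- ga %in% bmsc_genes
    b_m <- gb %in% bmsc_genes
    if (ga == gb) {
      if ("self_ligand" %in% classes && (a_b || a_m))
        emit(gene_a = ga, gene_b = gb, class = "self_ligand",
             b_gene = if (a_b) ga else NA_character_,
             b_direction = if (a_b) unname(b_set[ga]) else NA_character_,
             bmsc_gene = if (a_m) ga else NA_character_,
             bmsc_clusters = if (a_m) paste(bmsc_map[[ga]], collapse = ",")
                             else NA_character_,
             dual = a_b && a_m, confidence = conf)
      next
    }
    if ("B_B" %in% classes && a_b && b_b)
      emit(gene_a = ga, gene_b = gb, class = "B_B",
           b_gene = paste(ga, gb, sep = ","),
           b_direction = paste(unname(b_set[c(ga, gb)]), collapse = ","),
           bmsc_gene = NA_character_, bmsc_clusters = NA_character_,
           dual = a_m || b_m, confidence = conf)
    if ("B_BMSC" %in% classes) {
      if (a_b && b_m)
        emit(gene_a = ga, gene_b = gb, class = "B_BMSC",
             b_gene = ga, b_direction = unname(b_set[ga]),
             bmsc_gene = gb,
             bmsc_clusters = paste(bmsc_map[[gb]], collapse = ","),
             dual = a_m || b_b, confidence = conf)
      if (b_b && a_m)
        emit(gene_a = ga, gene_b = gb, class = "B_BMSC",
             b_gene = gb, b_direction = unname(b_set[gb]),
             bmsc_gene = ga,
             bmsc_clusters = paste(bmsc_map[[ga]], collapse = ","),
             dual = a_b || b_m, confidence = conf)
    }
  }
  if (length(rec) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      class = character(0), b_gene = character(0),
                      b_direction = character(0), bmsc_gene = character(0),
                      bmsc_clusters = character(0), dual = logical(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rec)
  out <- out[order(out$class, out$gene_a, out$gene_b, out$b_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Condition composition and exclusivity of clusters
#'
#' For each cluster, counts cells per experimental condition and reports
#' the exclusivity (largest condition fraction) with the dominant
#' condition. Clusters reaching `exclusive_min` are flagged
#' condition-exclusive — the logic that identifies a stromal cluster
#' consisting solely of cells that had tumor contact.
#'
#' @param assignments Vector: cluster id per cell.
#' @param conditions Vector: condition label per cell (same length).
#' @param exclusive_min Exclusivity needed for the flag (default 0.95).
#' @return Data frame: `cluster`, `n_cells`, `exclusivity`,
#'   `dominant_condition`, `exclusive`, plus one `n_<condition>` column per
#'   condition.
#' @export
condition_exclusivity <- function(assignments, conditions,
                                  exclusive_min = 0.95) {
  stopifnot(length(assignments) == length(conditions))
  if (anyNA(conditions))
    stop("every assigned cell must have a condition", call. = FALSE)
  keep <- !is.na(assignments)
  if (any(!keep)) {
    warning(sprintf("%d unassigned cell(s) excluded", sum(!keep)))
    assignments <- assignments[keep]
    conditions <- conditions[keep]
  }
  tab <- table(cluster = assignments, condition = conditions)
  if (nrow(tab) == 0L)
    return(data.frame(cluster = character(0), n_cells = integer(0),
                      exclusivity = numeric(0),
                      dominant_condition = character(0),
                      exclusive = logical(0)))
  n_cells <- rowSums(tab)
  frac <- tab / n_cells
  excl <- apply(frac, 1, max)
  dom <- colnames(tab)[apply(frac, 1, which.max)]
  out <- data.frame(
    cluster = rownames(tab),
    n_cells = as.integer(n_cells),
    exclusivity = as.numeric(excl),
    dominant_condition = dom,
    exclusive = as.numeric(excl) >= exclusive_min,
    stringsAsFactors = FALSE
  )
  for (cond in colnames(tab)) out[[paste0("n_", cond)]] <- as.integer(tab[, cond])
  rownames(out) <- NULL
  out
}
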