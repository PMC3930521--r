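# mtDNA haplotype collapsing and sequence diversity statistics.
#
# Site handling follows the Arlequin-compatible convention: a column that
# contains a gap, an N, or any other ambiguity code in ANY analysed sequence
# is excluded ("comparable sites", complete deletion) for haplotype collapsing
# and diversity; pairwise distances use pairwise deletion instead.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)

encode_alignment <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  code <- matrix(0L, nrow(m), ncol(m), dimnames = list(aln$id, NULL))
  for (b in names(BASE_CODE)) code[m == b] <- BASE_CODE[[b]]
  code
}

comparable_cols <- function(code) which(colSums(code == 0L) == 0L)

#' Indices of variable and parsimony-informative sites
#'
#' Sites are assessed over comparable columns only (columns containing a gap
#' or ambiguity in any sequence are skipped). A site is variable when at least
#' two bases are observed; parsimony-informative when at least two bases are
#' each carried by at least two sequences.
#'
#' @param aln Alignment tibble.
#' @return A list with integer vectors `variable` and `informative` (1-based
#'   positions in the original alignment) and `comparable`, the comparable
#'   column indices.
#' @export
variable_sites <- function(aln) {
  code <- encode_alignment(aln)
  comp <- comparable_cols(code)
  is_var <- logical(length(comp))
  is_inf <- logical(length(comp))
  for (k in seq_along(comp)) {
    tab <- tabulate(code[, comp[k]], nbins = 4L)
    states <- sum(tab > 0L)
    is_var[k] <- states >= 2L
    is_inf[k] <- sum(tab >= 2L) >= 2L && states >= 2L
  }
  list(variable = comp[is_var], informative = comp[is_inf], comparable = comp)
}

#' Collapse aligned sequences into haplotypes
#'
#' Haplotypes are distinct rows of the alignment restricted to comparable
#' sites. Haplotype labels `H1, H2, ...` are assigned by decreasing total
#' frequency (ties by first appearance).
#'
#' @param aln Alignment tibble.
#' @param popmap Optional population map; when given, per-site and per-group
#'   counts are tabulated.
#' @return An object of class `haplotype_table`: a list with tibbles
#'   `haplotypes` (haplotype, representative sequence, n), `membership`
#'   (id, haplotype), `counts` (haplotype x site/group counts, if `popmap`
#'   given), and the comparable site indices.
#' @export
collapse_haplotypes <- function(aln, popmap = NULL) {
  code <- encode_alignment(aln)
  comp <- comparable_cols(code)
  if (!length(comp)) abort("no comparable sites in alignment")
  key <- apply(code[, comp, drop = FALSE], 1, paste, collapse = ".")
  first <- !duplicated(key)
  counts <- table(factor(key, levels = key[first]))
  ord <- order(-as.integer(counts), seq_along(counts))
  labels <- stats::setNames(paste0("H", order(ord)), names(counts))
  hap_of <- unname(labels[key])
  haps <- tibble(
    haplotype = unname(labels[names(counts)]),
    sequence = aln$seq[first],
    n = as.integer(counts)
  ) |> arrange(as.integer(sub("^H", "", .data$haplotype)))
  membership <- tibble(id = aln$id, haplotype = hap_of)
  cnt <- NULL
  if (!is.null(popmap)) {
    pm <- validate_popmap(aln$id, popmap)
    cnt <- membership |>
      left_join(popmap, by = "id") |>
      count(.data$haplotype, .data$site, .data$group, name = "n")
  }
  structure(list(haplotypes = haps, membership = membership, counts = cnt,
                 comparable = comp, L = attr(aln, "L")),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$haplotypes), " haplotypes from ",
      nrow(x$membership), " sequences (", length(x$comparable),
      " comparable sites)\n", sep = "")
  print(x$haplotypes, n = 5)
  invisible(x)
}

#' @export
tidy.haplotype_table <- function(x, ...) {
  if (is.null(x$counts)) x$haplotypes else x$counts
}

#' Count fixed differences between two groups
#'
#' A site is a fixed difference when the sets of bases observed in the two
#' groups are non-empty and disjoint (gaps/ambiguities ignored per site).
#'
#' @param aln Alignment tibble.
#' @param popmap Population map with exactly two groups among the aligned
#'   individuals.
#' @param level Column of `popmap` defining the two partitions (default
#'   `"group"`).
#' @return Integer count of fixed-difference sites.
#' @export
fixed_differences <- function(aln, popmap, level = "group") {
  pm <- validate_popmap(aln$id, popmap)
  lab <- pm[[level]]
  groups <- unique(lab)
  if (length(groups) != 2) abort("exactly two groups are required")
  code <- encode_alignment(aln)
  idx1 <- which(lab == groups[1])
  idx2 <- which(lab == groups[2])
  if (!length(idx1) || !length(idx2)) abort("a group has zero sequences")
  fixed <- 0L
  for (s in seq_len(ncol(code))) {
    b1 <- unique(code[idx1, s]); b1 <- b1[b1 > 0L]
    b2 <- unique(code[idx2, s]); b2 <- b2[b2 > 0L]
    if (length(b1) && length(b2) && !length(intersect(b1, b2))) fixed <- fixed + 1L
  }
  fixed
}

#' Haplotype (gene) diversity
#'
#' `h = n/(n-1) * (1 - sum p_i^2)` over haplotype frequencies: the
#' sample-size-corrected probability that two randomly drawn sequences carry
#' different haplotypes.
#'
#' @param counts Integer vector of haplotype counts (one entry per haplotype).
#' @return `h` in `[0, 1]`; `NA` with a warning when `n < 2`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    warn("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity
#'
#' Mean pairwise sequence difference per comparable site: for each of the
#' `n(n-1)/2` pairs the proportion of differing sites over sites comparable in
#' that pair (pairwise deletion), averaged over pairs.
#'
#' @param aln Alignment tibble (n >= 2).
#' @param per_site Divide by the pair's comparable length (default `TRUE`);
#'   with `FALSE` the mean absolute number of differences is returned.
#' @return Nucleotide diversity (per site by default).
#' @export
nucleotide_diversity <- function(aln, per_site = TRUE) {
  code <- encode_alignment(aln)
  n <- nrow(code)
  if (n < 2) {
    warn("nucleotide diversity undefined for n < 2")
    return(NA_real_)
  }
  tot <- 0
  for (i in seq_len(n - 1)) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      valid <- xi > 0L & xj > 0L
      nc <- sum(valid)
      d <- sum(xi[valid] != xj[valid])
      tot <- tot + if (per_site) {
        if (nc > 0) d / nc else 0
      } else d
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Per-site, per-group and overall mtDNA diversity summary
#'
#' Builds the standard diversity table: number of sequences (`n`), haplotypes
#' (`H`), private haplotypes (`PH`, observed at no other site / in no other
#' group), haplotype diversity (`h`) and nucleotide diversity (`pi`).
#'
#' @param aln Alignment tibble.
#' @param popmap Population map.
#' @return A tibble with one row per site, one per group (pooled) and one
#'   overall row; column `level` distinguishes them.
#' @export
diversity_summary <- function(aln, popmap) {
  pm <- validate_popmap(aln$id, popmap)
  ht <- collapse_haplotypes(aln, popmap)
  mem <- ht$membership |> left_join(popmap, by = "id")
  site_of_hap <- mem |> distinct(.data$haplotype, .data$site)
  n_sites_of_hap <- site_of_hap |> count(.data$haplotype, name = "n_sites")
  group_of_hap <- mem |> distinct(.data$haplotype, .data$group)
  n_groups_of_hap <- group_of_hap |> count(.data$haplotype, name = "n_groups")

  one_row <- function(ids, level, name) {
    sub <- aln[aln$id %in% ids, , drop = FALSE]
    attr(sub, "L") <- attr(aln, "L")
    hcounts <- mem |> filter(.data$id %in% ids) |> count(.data$haplotype)
    tibble(level = level, name = name, n = length(ids),
           H = nrow(hcounts),
           PH = NA_integer_,
           h = haplotype_diversity(hcounts$n),
           pi = if (length(ids) >= 2) nucleotide_diversity(sub) else NA_real_)
  }
  site_rows <- pm |>
    distinct(.data$site) |>
    pull(.data$site) |>
    map(function(s) {
      r <- one_row(pm$id[pm$site == s], "site", s)
      priv <- mem |> filter(.data$site == s) |> distinct(.data$haplotype) |>
        inner_join(n_sites_of_hap, by = "haplotype") |>
        filter(.data$n_sites == 1L)
      r$PH <- nrow(priv)
      r
    }) |> list_rbind()
  group_rows <- pm |>
    distinct(.data$group) |>
    pull(.data$group) |>
    map(function(g) {
      r <- one_row(pm$id[pm$group == g], "group", g)
      priv <- mem |> filter(.data$group == g) |> distinct(.data$haplotype) |>
        inner_join(n_groups_of_hap, by = "haplotype") |>
        filter(.data$n_groups == 1L)
      r$PH <- nrow(priv)
      r
    }) |> list_rbind()
  overall <- one_row(pm$id, "overall", "overall")
  overall$PH <- 0L
  bind_rows(site_rows, group_rows, overall)
}
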