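#' Build a validated sequence alignment tibble
#'
#' The package represents a multiple alignment as a tibble with one row per
#' sequence and columns `id` and `seq`. Sequences must be equal-length strings
#' over `A,C,G,T,-,N` (IUPAC ambiguity letters are accepted on input and
#' treated as `N` by downstream statistics).
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`).
#' @return A tibble with columns `id`, `seq` and attribute `L` (alignment
#'   length in bp).
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (!length(ids)) abort("empty alignment", class = "geelbek_format_error")
  if (length(ids) != length(seqs)) {
    abort("ids and sequences differ in length", class = "geelbek_format_error")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sequence ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "geelbek_format_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort(paste0("ragged alignment: sequence lengths ",
                 paste(sort(unique(lens)), collapse = ", ")),
          class = "geelbek_alignment_error")
  }
  if (lens[1] == 0) abort("zero-length sequences", class = "geelbek_alignment_error")
  bad <- grepl("[^ACGTUNRYSWKMBDHV?.-]", seqs)
  if (any(bad)) {
    abort(paste0("invalid characters in sequences: ",
                 paste(ids[bad], collapse = ", ")),
          class = "geelbek_alignment_error")
  }
  out <- tibble(id = ids, seq = seqs)
  attr(out, "L") <- unname(lens[1])
  out
}

#' Read an aligned FASTA file
#'
#' @param path Path to a FASTA file of equal-length aligned sequences.
#' @return An alignment tibble (see [alignment()]); lowercase bases are
#'   normalized to uppercase.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dna <- tryCatch(ape::read.FASTA(path),
                  error = function(e) abort(paste0("not a readable FASTA: ", path),
                                            class = "geelbek_format_error"))
  if (!length(dna)) abort("empty FASTA file", class = "geelbek_format_error")
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""), "")
  alignment(names(dna), seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  writeLines(paste0(">", aln$id, "\n", aln$seq), path)
  invisible(path)
}

# ---- genotypes ---------------------------------------------------------------

new_genotypes <- function(id, locus, allele_1, allele_2) {
  a1 <- as.integer(allele_1)
  a2 <- as.integer(allele_2)
  # unordered pair: store sorted, NA-pair for missing
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    abort("half-missing genotype calls (one allele scored, one missing)",
          class = "geelbek_format_error")
  }
  if (any(c(a1, a2) <= 0, na.rm = TRUE)) {
    abort("allele sizes must be positive integers", class = "geelbek_format_error")
  }
  tibble(id = as.character(id), locus = as.character(locus),
         allele_1 = a1, allele_2 = a2)
}

parse_genepop_allele <- function(x, width) {
  a <- suppressWarnings(as.integer(substr(x, 1, width)))
  b <- suppressWarnings(as.integer(substr(x, width + 1, 2 * width)))
  list(a = ifelse(is.na(a) | a == 0L, NA_integer_, a),
       b = ifelse(is.na(b) | b == 0L, NA_integer_, b))
}

#' Read a diploid microsatellite genotype table
#'
#' Two dialects are supported. `"genepop"` reads the classic GenePop layout
#' (title line, locus names one per line or comma-separated, `Pop` separators,
#' individual lines `id , 0102 0304 ...`) with 2- or 3-digit allele coding;
#' `0000`/`000000` and blank calls become missing. `"tsv"` reads a wide table
#' whose first column is the individual id and remaining columns are loci with
#' entries `"152/154"` (empty or `NA` for missing).
#'
#' @param path Input file.
#' @param dialect `"genepop"` or `"tsv"`.
#' @return A long tibble with columns `id`, `locus`, `allele_1`, `allele_2`
#'   (both alleles `NA` when missing; `allele_1 <= allele_2`). For GenePop
#'   input the population blocks are returned as a `pop_blocks` attribute
#'   (list of id vectors in file order).
#' @export
read_genotypes <- function(path, dialect = c("genepop", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") return(read_genotypes_tsv(path))

  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) abort("truncated GenePop file", class = "geelbek_format_error")
  body <- lines[-1]                        # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("GenePop file has no Pop line", class = "geelbek_format_error")
  loc_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(paste(loc_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) abort("GenePop file lists no loci", class = "geelbek_format_error")

  rows <- list()
  blocks <- list()
  pop_i <- 0L
  for (ln in body[first_pop:length(body)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_i <- pop_i + 1L
      blocks[[pop_i]] <- character()
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) {
      abort(paste0("malformed GenePop individual line: ", ln),
            class = "geelbek_format_error")
    }
    ind <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(calls) != length(loci)) {
      abort(paste0("individual ", ind, " has ", length(calls),
                   " genotype fields for ", length(loci), " loci"),
            class = "geelbek_format_error")
    }
    width <- nchar(calls[1]) / 2
    if (!all(nchar(calls) %in% c(4L, 6L)) || width != round(width)) {
      abort(paste0("individual ", ind, ": allele coding must be 2- or 3-digit"),
            class = "geelbek_format_error")
    }
    al <- parse_genepop_allele(calls, nchar(calls) / 2)
    rows[[length(rows) + 1L]] <- tibble(id = ind, locus = loci,
                                        allele_1 = al$a, allele_2 = al$b)
    blocks[[pop_i]] <- c(blocks[[pop_i]], ind)
  }
  gt <- bind_rows(rows)
  gt <- new_genotypes(gt$id, gt$locus, gt$allele_1, gt$allele_2)
  attr(gt, "pop_blocks") <- blocks
  gt
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) abort("genotype TSV needs an id column plus loci",
                           class = "geelbek_format_error")
  names(tab)[1] <- "id"
  long <- tidyr::pivot_longer(tab, -"id", names_to = "locus", values_to = "call")
  bad <- !is.na(long$call) & nzchar(long$call) & !grepl("^\\d+/\\d+$", long$call)
  if (any(bad)) {
    abort(paste0("unparseable genotype calls, e.g. '", long$call[bad][1], "'"),
          class = "geelbek_format_error")
  }
  a <- ifelse(is.na(long$call) | !nzchar(long$call), NA_character_,
              sub("/.*", "", long$call))
  b <- ifelse(is.na(long$call) | !nzchar(long$call), NA_character_,
              sub(".*/", "", long$call))
  new_genotypes(long$id, long$locus, a, b)
}

#' Write genotypes in GenePop format
#'
#' @param gt Genotype tibble (see [read_genotypes()]).
#' @param path Output path.
#' @param popmap Optional population map; individuals are grouped into `Pop`
#'   blocks by site (file order follows the popmap). Without it a single
#'   population block is written.
#' @param digits Allele field width, 2 or 3 (default 3).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, popmap = NULL, digits = 3, title = "geelbek export") {
  loci <- unique(gt$locus)
  wide <- tidyr::pivot_wider(gt, names_from = "locus",
                             values_from = c("allele_1", "allele_2"))
  ids <- wide$id
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  line_of <- function(i) {
    calls <- vapply(loci, function(l) {
      paste0(fmt(wide[[paste0("allele_1_", l)]][i]),
             fmt(wide[[paste0("allele_2_", l)]][i]))
    }, "")
    paste0(ids[i], " , ", paste(calls, collapse = " "))
  }
  if (is.null(popmap)) {
    groups <- list(seq_along(ids))
  } else {
    sites <- popmap$site[match(ids, popmap$id)]
    groups <- split(seq_along(ids), factor(sites, levels = unique(sites)))
  }
  out <- c(title, loci)
  for (g in groups) out <- c(out, "Pop", vapply(g, line_of, ""))
  writeLines(out, path)
  invisible(path)
}

# ---- population map ----------------------------------------------------------

#' Read a two-level population map
#'
#' A population map assigns each individual to a sampling site and each site
#' to a region/group (e.g. northern vs southern subsystem). Accepted layouts:
#' a single 3-column TSV `individual site group`; or a 2-column
#' `individual site` section followed (after a blank line) by a 2-column
#' `site group` section; or a 2-column file plus a separate `groups` file or
#' named vector (`site -> group`).
#'
#' @param path Path to the map file (no header).
#' @param groups Optional site-to-group assignment: a path to a 2-column TSV,
#'   or a named character vector `c(site = group)`.
#' @return A tibble with columns `id`, `site`, `group`.
#' @export
read_popmap <- function(path, groups = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  blank <- grepl("^\\s*$", lines)
  split_at <- which(blank)[1]
  parse_two <- function(ls) {
    ls <- ls[!grepl("^\\s*$", ls)]
    parts <- strsplit(ls, "\t")
    n <- lengths(parts)
    list(parts = parts, n = n)
  }
  p1 <- parse_two(if (is.na(split_at)) lines else lines[seq_len(split_at - 1)])
  if (all(p1$n == 3)) {
    pm <- tibble(id = vapply(p1$parts, `[`, "", 1),
                 site = vapply(p1$parts, `[`, "", 2),
                 group = vapply(p1$parts, `[`, "", 3))
    return(validate_popmap_tbl(pm))
  }
  if (!all(p1$n == 2)) {
    abort("population map rows must have 2 or 3 tab-separated fields",
          class = "geelbek_format_error")
  }
  pm <- tibble(id = vapply(p1$parts, `[`, "", 1),
               site = vapply(p1$parts, `[`, "", 2))
  g <- NULL
  if (!is.na(split_at)) {
    p2 <- parse_two(lines[(split_at + 1):length(lines)])
    if (length(p2$parts) && all(p2$n == 2)) {
      g <- stats::setNames(vapply(p2$parts, `[`, "", 2),
                           vapply(p2$parts, `[`, "", 1))
    }
  }
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
      p2 <- parse_two(readLines(groups))
      g <- stats::setNames(vapply(p2$parts, `[`, "", 2),
                           vapply(p2$parts, `[`, "", 1))
    } else if (!is.null(names(groups))) {
      g <- groups
    } else {
      abort("groups must be a 2-column TSV path or a named vector")
    }
  }
  if (is.null(g)) g <- stats::setNames(rep("all", length(unique(pm$site))),
                                       unique(pm$site))
  unmapped <- setdiff(pm$site, names(g))
  if (length(unmapped)) {
    abort(paste0("sites missing a group assignment: ",
                 paste(unmapped, collapse = ", ")),
          class = "geelbek_validation_error")
  }
  pm$group <- unname(g[pm$site])
  validate_popmap_tbl(pm)
}

validate_popmap_tbl <- function(pm) {
  if (anyDuplicated(pm$id)) {
    abort(paste0("individuals mapped more than once: ",
                 paste(unique(pm$id[duplicated(pm$id)]), collapse = ", ")),
          class = "geelbek_validation_error")
  }
  as_tibble(pm[c("id", "site", "group")])
}

#' Check that every analysed individual is present in the population map
#'
#' @param ids Character vector of individual ids (or an alignment/genotype
#'   tibble, whose `id` column is used).
#' @param popmap Population map tibble.
#' @return The matching rows of `popmap`, in the order of `ids`, invisibly
#'   usable downstream. Errors listing the offending ids if any are unmapped.
#' @export
validate_popmap <- function(ids, popmap) {
  if (is.data.frame(ids)) ids <- unique(ids$id)
  missing <- setdiff(ids, popmap$id)
  if (length(missing)) {
    abort(paste0("individuals absent from the population map: ",
                 paste(missing, collapse = ", ")),
          class = "geelbek_validation_error")
  }
  popmap[match(ids, popmap$id), ]
}
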