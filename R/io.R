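#' Read unphased genotypes from PED/MAP or the tabular dialect
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`ped_map`}{white-space delimited PED with the six leading columns
#'     (family, individual, father, mother, sex, phenotype) followed by two
#'     allele calls per SNP (`0 0` = missing), plus a MAP file (chromosome,
#'     snp id, genetic distance, position). The family id is taken as the
#'     cohort label and the PED sex column (1 = male, 2 = female) is retained
#'     as an attribute.}
#'   \item{`tabular`}{tab-delimited matrix: a comment line
#'     `#count_allele<TAB>snp=allele...`, a header row of snp ids, then one row
#'     per individual with columns `individual_id`, `cohort` and the 0/1/2/NA
#'     dosage of the count allele.}
#' }
#'
#' Counts are oriented to the minor allele computed over the loaded sample,
#' unless `count_allele` designates the allele to count per SNP.
#'
#' @param path for `ped_map`, the `.ped` file (the `.map` is looked up next to
#'   it) or a prefix; for `tabular`, the file itself.
#' @param format `"ped_map"` or `"tabular"`.
#' @param count_allele optional named character vector fixing the counted
#'   allele per SNP.
#' @return list with elements `genotypes` (a [geno_matrix()]), `panel` (a
#'   minimal SNP annotation: id, chromosome, position, allele pair) and `sex`
#'   (named vector, `ped_map` only).
#' @export
read_genotypes <- function(path, format = c("ped_map", "tabular"),
                           count_allele = NULL) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path, count_allele)
  else read_tabular(path, count_allele)
}

ped_paths <- function(path) {
  if (grepl("\\.ped$", path)) {
    list(ped = path, map = sub("\\.ped$", ".map", path))
  } else {
    list(ped = paste0(path, ".ped"), map = paste0(path, ".map"))
  }
}

read_ped_map <- function(path, count_allele = NULL) {
  pp <- ped_paths(path)
  for (f in unlist(pp)) if (!file.exists(f)) stopf("file not found: %s", f)
  map_lines <- readLines(pp$map)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines) == 0L) stopf("parse error: %s is empty", pp$map)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad)) stopf("parse error in %s line %d: expected 4 fields",
                         pp$map, bad[1])
  map <- data.frame(
    chromosome = vapply(map_tok, `[`, "", 1L),
    snp_id     = vapply(map_tok, `[`, "", 2L),
    position   = as.integer(vapply(map_tok, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  n_snp <- nrow(map)

  ped_lines <- readLines(pp$ped)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (length(ped_lines) == 0L) stopf("parse error: %s is empty", pp$ped)
  tok <- strsplit(trimws(ped_lines), "[ \t]+")
  bad <- which(lengths(tok) != 6L + 2L * n_snp)
  if (length(bad)) stopf("parse error in %s line %d: expected %d fields, got %d",
                         pp$ped, bad[1], 6L + 2L * n_snp, lengths(tok)[bad[1]])
  tokm <- do.call(rbind, tok)
  ids <- tokm[, 2L]
  cohort <- stats::setNames(tokm[, 1L], ids)
  sex_code <- tokm[, 5L]
  sex <- stats::setNames(ifelse(sex_code == "1", "male",
                                ifelse(sex_code == "2", "female", NA)), ids)
  a1 <- tokm[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- tokm[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  bad_allele <- unique(c(a1, a2))
  bad_allele <- setdiff(bad_allele, c(VALID_ALLELES, "0"))
  if (length(bad_allele))
    stopf("validation error: allele code(s) not in {A,C,G,T,0}: %s",
          paste(bad_allele, collapse = ", "))
  build_geno(ids, cohort, map, a1, a2, count_allele, sex)
}

# shared by both readers once calls are in two allele matrices
build_geno <- function(ids, cohort, map, a1, a2, count_allele, sex = NULL) {
  n_snp <- nrow(map)
  counts <- matrix(NA_integer_, nrow = length(ids), ncol = n_snp,
                   dimnames = list(ids, map$snp_id))
  cnt_allele <- character(n_snp)
  for (j in seq_len(n_snp)) {
    c1 <- a1[, j]; c2 <- a2[, j]
    miss <- c1 == "0" | c2 == "0"
    obs <- c(c1[!miss], c2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stopf("validation error: SNP %s has >2 alleles: %s",
            map$snp_id[j], paste(alleles, collapse = ","))
    target <- if (!is.null(count_allele) && !is.na(count_allele[map$snp_id[j]])) {
      count_allele[[map$snp_id[j]]]
    } else if (length(alleles) == 0L) {
      "A"  # all-missing column; arbitrary but fixed
    } else if (length(alleles) == 1L) {
      alleles
    } else {
      freq1 <- mean(obs == alleles[1])
      if (freq1 <= 0.5) alleles[1] else alleles[2]
    }
    cnt_allele[j] <- target
    g <- (c1 == target) + (c2 == target)
    g[miss] <- NA_integer_
    counts[, j] <- as.integer(g)
  }
  names(cnt_allele) <- map$snp_id
  other <- vapply(seq_len(n_snp), function(j) {
    c1 <- a1[, j]; c2 <- a2[, j]
    obs <- setdiff(unique(c(c1, c2)), c("0", cnt_allele[j]))
    if (length(obs) >= 1L) obs[1] else complement_allele(cnt_allele[j])
  }, "")
  panel <- data.frame(
    snp_id = map$snp_id, gene = NA_character_,
    chromosome = map$chromosome, position = map$position,
    allele_a1 = unname(cnt_allele), allele_a2 = other,
    is_tag = NA, stringsAsFactors = FALSE
  )
  g <- geno_matrix(counts, cnt_allele, cohort)
  list(genotypes = g, panel = panel, sex = sex)
}

read_tabular <- function(path, count_allele = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stopf("parse error: %s is empty", path)
  ca <- NULL
  if (startsWith(lines[1], "#count_allele")) {
    fields <- strsplit(lines[1], "\t")[[1]][-1]
    kv <- strsplit(fields, "=", fixed = TRUE)
    ca <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    lines <- lines[-1]
  }
  tok <- strsplit(lines, "\t", fixed = TRUE)
  header <- tok[[1]]
  if (length(header) < 3L || header[1] != "individual_id" || header[2] != "cohort")
    stopf("parse error in %s line 1: expected header 'individual_id\tcohort\t<snp ids>'", path)
  snp_ids <- header[-(1:2)]
  body <- tok[-1]
  bad <- which(lengths(body) != length(header))
  if (length(bad)) stopf("parse error in %s line %d: expected %d fields",
                         path, bad[1] + 1L + !is.null(ca), length(header))
  bm <- do.call(rbind, body)
  ids <- bm[, 1L]
  cohort <- stats::setNames(bm[, 2L], ids)
  cells <- bm[, -(1:2), drop = FALSE]
  ok <- cells %in% c("0", "1", "2", "NA")
  if (!all(ok)) stopf("validation error: tabular cells must be 0/1/2/NA (found '%s')",
                      cells[!ok][1])
  counts <- matrix(suppressWarnings(as.integer(cells)),
                   nrow = nrow(cells), dimnames = list(ids, snp_ids))
  if (is.null(ca)) {
    if (is.null(count_allele))
      stopf("tabular file lacks a #count_allele line and no count_allele was supplied")
    ca <- count_allele
  }
  ca <- ca[snp_ids]
  if (anyNA(ca)) stopf("count allele missing for: %s",
                       paste(snp_ids[is.na(ca)], collapse = ", "))
  # re-orientation if the caller designates the partner allele is not possible
  # without the allele pair; tabular counts are taken at face value
  panel <- data.frame(
    snp_id = snp_ids, gene = NA_character_, chromosome = NA_character_,
    position = NA_integer_, allele_a1 = unname(ca),
    allele_a2 = complement_allele(unname(ca)), is_tag = NA,
    stringsAsFactors = FALSE
  )
  list(genotypes = geno_matrix(counts, ca, cohort), panel = panel, sex = NULL)
}

#' Write genotypes to PED/MAP or the tabular dialect
#'
#' Inverse of [read_genotypes()]: `write_genotypes` followed by
#' `read_genotypes` (with the same `count_allele`) reproduces counts, ids and
#' alleles exactly.
#'
#' @param geno a [geno_matrix()].
#' @param path output prefix (`ped_map`) or file (`tabular`).
#' @param format `"ped_map"` or `"tabular"`.
#' @param panel SNP annotation supplying the partner allele, chromosome and
#'   position (required for `ped_map`).
#' @param sex optional named `"male"`/`"female"` vector for the PED sex column.
#' @return the path(s) written, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("ped_map", "tabular"),
                            panel = NULL, sex = NULL) {
  format <- match.arg(format)
  if (format == "tabular") {
    snp_ids <- colnames(geno$counts)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#count_allele\t",
                      paste(snp_ids, geno$count_allele[snp_ids],
                            sep = "=", collapse = "\t")), con)
    writeLines(paste(c("individual_id", "cohort", snp_ids), collapse = "\t"), con)
    body <- cbind(rownames(geno$counts), unname(geno$cohort),
                  ifelse(is.na(geno$counts), "NA", geno$counts))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    return(invisible(path))
  }
  if (is.null(panel)) stopf("ped_map output needs a panel with allele pairs")
  pp <- ped_paths(path)
  m <- match(colnames(geno$counts), panel$snp_id)
  if (anyNA(m)) stopf("SNPs absent from panel: %s",
                      paste(colnames(geno$counts)[is.na(m)], collapse = ", "))
  pr <- panel[m, , drop = FALSE]
  other <- ifelse(geno$count_allele[colnames(geno$counts)] == pr$allele_a1,
                  pr$allele_a2, pr$allele_a1)
  n <- nrow(geno$counts)
  sex_col <- rep("0", n)
  if (!is.null(sex)) {
    s <- sex[rownames(geno$counts)]
    sex_col <- ifelse(s == "male", "1", ifelse(s == "female", "2", "0"))
  }
  lines <- vapply(seq_len(n), function(i) {
    g <- geno$counts[i, ]
    cnt <- geno$count_allele[colnames(geno$counts)]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, cnt, other))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, cnt, other))
    paste(c(geno$cohort[[i]], rownames(geno$counts)[i], "0", "0",
            sex_col[i], "-9", as.vector(rbind(a1, a2))), collapse = " ")
  }, "")
  writeLines(lines, pp$ped)
  writeLines(sprintf("%s %s 0 %d", pr$chromosome, pr$snp_id, pr$position), pp$map)
  invisible(unlist(pp))
}

#' Read/write the phenotype TSV used by the pipeline
#'
#' Plain tab-delimited table with header `individual_id cohort age sex bmi dm2`.
#'
#' @param path file path.
#' @rdname phenotype_io
#' @return `read_phenotypes`: a validated [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$dm2 <- as.logical(df$dm2)
  phenotype_table(df)
}

#' @param df phenotype data.frame.
#' @rdname phenotype_io
#' @export
write_phenotypes <- function(df, path) {
  utils::write.table(df[, setdiff(names(df), "obesity")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
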