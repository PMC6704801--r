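#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a tidy table of sequence records. Sequences are
#' uppercased, folded lines are joined and record order is preserved. The id
#' of a record is the first whitespace-delimited token of its header.
#'
#' @param path Path to a FASTA file.
#' @param moltype Either `"protein"` or `"dna"`; the declared molecule type
#'   is validated against the sequence alphabet (`X` allowed for protein,
#'   `N` for dna).
#' @return A tibble with columns `id`, `seq` and `moltype`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MK", "WQ"), fa)
#' read_fasta(fa, "protein")
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("could not parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no records in FASTA file '", path, "'"))
  ids <- vapply(strsplit(trimws(names(set)), "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort(paste0("empty sequence for id '", ids[empty[1]], "'"))
  }
  check_alphabet(seqs, ids, moltype)
  tibble(id = unname(ids), seq = unname(seqs), moltype = moltype)
}

seq_alphabet <- function(moltype) {
  switch(moltype,
    protein = "ACDEFGHIKLMNPQRSTVWYX*",
    dna = "ACGTN"
  )
}

check_alphabet <- function(seqs, ids, moltype) {
  pat <- paste0("[^", seq_alphabet(moltype), "]")
  bad <- regexpr(pat, seqs)
  hit <- which(bad > 0)
  if (length(hit) > 0) {
    i <- hit[1]
    abort(paste0(
      "illegal ", moltype, " residue '", substr(seqs[i], bad[i], bad[i]),
      "' at position ", bad[i], " in sequence '", ids[i], "'"
    ))
  }
  invisible(TRUE)
}

#' Write sequence records to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `seq` (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Consumes only rows whose feature type is `gene`. GFF3 1-based inclusive
#' coordinates are converted to the package-internal 0-based half-open
#' convention; the gene id is taken from the `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (length(lineno) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(paste0("malformed GFF3 row at line ", lineno[which(nf < 9)[1]], ": fewer than 9 columns"))
  }
  gff <- tibble(
    line = lineno,
    chrom = vapply(fields, `[`, character(1), 1),
    type = vapply(fields, `[`, character(1), 3),
    start1 = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4))),
    end1 = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 5))),
    strand = vapply(fields, `[`, character(1), 7),
    attr = vapply(fields, `[`, character(1), 9)
  )
  gff <- filter(gff, .data$type == "gene")
  if (nrow(gff) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  bad <- which(is.na(gff$start1) | is.na(gff$end1) | gff$start1 > gff$end1)
  if (length(bad) > 0) {
    abort(paste0("invalid coordinates (start > end) at line ", gff$line[bad[1]]))
  }
  id <- stringr::str_match(gff$attr, "(?:^|;)\\s*ID=([^;]+)")[, 2]
  noid <- which(is.na(id))
  if (length(noid) > 0) {
    abort(paste0("gene row missing ID attribute at line ", gff$line[noid[1]]))
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate gene_id: ", id[duplicated(id)][1]))
  }
  bad_strand <- which(!gff$strand %in% c("+", "-", "."))
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand '", gff$strand[bad_strand[1]], "' at line ", gff$line[bad_strand[1]]))
  }
  tibble(
    gene_id = id, chrom = gff$chrom,
    start = gff$start1 - 1L, end = gff$end1,
    strand = gff$strand
  )
}

#' Convert between GFF3 and internal interval coordinates
#'
#' Internal intervals are 0-based half-open on the forward strand; GFF3 is
#' 1-based inclusive. The two functions are exact inverses.
#'
#' @param x A data frame with integer columns `start` and `end`.
#' @return `x` with converted `start`/`end`.
#' @export
from_gff_coords <- function(x) {
  mutate(x, start = .data$start - 1L)
}

#' @rdname from_gff_coords
#' @export
to_gff_coords <- function(x) {
  mutate(x, start = .data$start + 1L)
}

#' Write gene models to GFF3
#'
#' Emits internal 0-based half-open gene intervals back to 1-based
#' inclusive GFF3 `gene` rows.
#'
#' @param genes A tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, source = "fiberfam") {
  rows <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    genes$chrom, source, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

# required columns per table kind; extra columns are always preserved
fiberfam_schemas <- list(
  qtl = c("qtl_id", "trait", "chrom"),
  marker_anchor = c("marker_id", "chrom", "cm", "bp"),
  allele_matrix = c("gene_id", "site_id"),
  genotype = c("line_id", "marker_id", "genotype"),
  phenotype = c("line_id", "environment", "trait", "value"),
  expression = c("gene_id", "allele", "stage", "value"),
  ct = c("sample", "gene", "ct")
)

#' Column roles for a multi-assembly allele matrix
#'
#' Maps the classification roles used by [classify_snp_sites()] onto the
#' columns of an allele matrix. The default matches the packaged fixture:
#' two reference assemblies of the recurrent species (*G. hirsutum* TM-1
#' by NAU and JGI), the two BIL parents (CCRI 36 and Hai 7124), the donor
#' parent's own assembly (Hai 7124 by ZJU) and two further donor-species
#' assemblies (Xinhai 21 and 3-79).
#'
#' @param speciesA_refs,speciesA_parent,speciesB_parent,speciesB_own,speciesB_other
#'   Column names carrying each role.
#' @return A named list of column names.
#' @export
table1_roles <- function(speciesA_refs = c("tm1_nau", "tm1_jgi"),
                         speciesA_parent = "ccri36",
                         speciesB_parent = "hai7124",
                         speciesB_own = "hai7124_zju",
                         speciesB_other = c("xinhai21_nau", "x3_79_hau")) {
  list(
    speciesA_refs = speciesA_refs,
    speciesA_parent = speciesA_parent,
    speciesB_parent = speciesB_parent,
    speciesB_own = speciesB_own,
    speciesB_other = speciesB_other
  )
}

#' Read and validate a pipeline table
#'
#' Reads a comma-separated file (UTF-8, `.` decimal separator) and enforces
#' the schema for the given table kind. Empty cells and `"NA"` are the
#' missing codes for numeric fields; `"N"` is the missing allele code.
#'
#' @param path Path to a CSV file with a header row.
#' @param kind One of `"qtl"`, `"marker_anchor"`, `"allele_matrix"`,
#'   `"genotype"`, `"phenotype"`, `"expression"`, `"ct"`.
#' @param roles For `kind = "allele_matrix"`, the role map (see
#'   [table1_roles()]) naming the allele columns to validate.
#' @return A validated tibble; extra columns are preserved.
#' @export
read_table <- function(path, kind, roles = table1_roles()) {
  kind <- match.arg(kind, names(fiberfam_schemas))
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  validate_table(df, kind, roles = roles)
}

#' Validate an in-memory pipeline table
#'
#' @param df A data frame.
#' @inheritParams read_table
#' @return The validated tibble (typed and with allele `NA` recoded to
#'   `"N"` for allele matrices).
#' @export
validate_table <- function(df, kind, roles = table1_roles()) {
  kind <- match.arg(kind, names(fiberfam_schemas))
  req <- fiberfam_schemas[[kind]]
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "table of kind '", kind, "' is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df <- as_tibble(df)
  if (kind == "qtl") {
    if (!("cm" %in% names(df)) && !all(c("cm_start", "cm_end") %in% names(df))) {
      abort("qtl table needs a 'cm' column or both 'cm_start' and 'cm_end'")
    }
    for (col in intersect(c("cm", "cm_start", "cm_end"), names(df))) {
      df[[col]] <- as_numeric_checked(df[[col]], col)
      if (any(df[[col]] < 0, na.rm = TRUE)) abort(paste0("negative cM in column '", col, "'"))
    }
  } else if (kind == "marker_anchor") {
    df$cm <- as_numeric_checked(df$cm, "cm")
    df$bp <- as_numeric_checked(df$bp, "bp")
  } else if (kind == "allele_matrix") {
    allele_cols <- unlist(roles, use.names = FALSE)
    missing_alleles <- setdiff(allele_cols, names(df))
    if (length(missing_alleles) > 0) {
      abort(paste0(
        "allele_matrix is missing allele column(s): ",
        paste(missing_alleles, collapse = ", ")
      ))
    }
    for (col in allele_cols) {
      v <- toupper(ifelse(is.na(df[[col]]), "N", as.character(df[[col]])))
      bad <- which(!v %in% c("A", "C", "G", "T", "-", "N"))
      if (length(bad) > 0) {
        abort(paste0(
          "non-allele character '", df[[col]][bad[1]], "' in column '", col,
          "', row ", bad[1]
        ))
      }
      df[[col]] <- v
    }
  } else if (kind == "genotype") {
    g <- suppressWarnings(as.numeric(df$genotype))
    bad <- which(!is.na(df$genotype) & (is.na(g) | !g %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(paste0("genotype must be 0, 1 or missing; offending row ", bad[1]))
    }
    df$genotype <- g
  } else if (kind %in% c("phenotype", "expression")) {
    df$value <- as_numeric_checked(df$value, "value")
  } else if (kind == "ct") {
    df$ct <- as_numeric_checked(df$ct, "ct")
  }
  df
}

as_numeric_checked <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0) {
    abort(paste0("non-numeric value '", x[bad[1]], "' in column '", col, "', row ", bad[1]))
  }
  v
}

#' Path to the packaged parental allele-matrix fixture
#'
#' The 27 nonsynonymous SNP sites in 17 MYB genes typed across seven
#' allele sources (two recurrent-species reference assemblies, the two
#' BIL parents, and three donor-species assemblies). The `snp_type`
#' column carries the published call and is not part of the input schema.
#'
#' @return Path to the installed CSV file.
#' @export
table1_fixture_path <- function() {
  system.file("extdata", "table1_allele_matrix.csv", package = "fiberfam", mustWork = TRUE)
}
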