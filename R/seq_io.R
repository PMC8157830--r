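# Sequence panels, FASTA/GenBank input, metadata, elementary nucleotide ops.
#
# A "panel" throughout this package is a plain data.frame with one row per
# sequence record and columns:
#   id          accession-like identifier, unique within the panel
#   description free-text header remainder
#   residues    upper-case IUPAC DNA string ('-' only in alignment context)
# plus optional metadata columns species, country, region_group,
# haplotype_label attached from a metadata TSV.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Normalize a nucleotide string
#'
#' Upper-cases, maps RNA-typed 'U' to 'T', and validates against the IUPAC
#' DNA alphabet. Gap characters ('-') are only accepted when
#' \code{allow_gap = TRUE} (alignment context); raw panels must be ungapped.
#'
#' @param s character scalar.
#' @param allow_gap logical; permit '-' characters.
#' @param what label used in error messages.
#' @return normalized string.
#' @keywords internal
normalize_dna <- function(s, allow_gap = FALSE, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- chartr("u", "t", toupper(s))
  s <- chartr("U", "T", s)
  ok <- IUPAC_LETTERS
  if (allow_gap) ok <- c(ok, "-")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop(sprintf("%s contains illegal character '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  if (!nzchar(s)) stop(what, " is empty", call. = FALSE)
  s
}

#' Construct a sequence panel
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of IUPAC DNA strings.
#' @param description optional character vector.
#' @param species,country,region_group optional metadata vectors.
#' @param allow_gap logical; permit alignment gaps in \code{residues}.
#' @return a panel data.frame.
#' @examples
#' seq_panel(c("a", "b"), c("ACGT", "ACGA"))
#' @export
seq_panel <- function(id, residues, description = "", species = NA_character_,
                      country = NA_character_, region_group = NA_character_,
                      allow_gap = FALSE) {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    stop("duplicate ids in panel: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  residues <- vapply(seq_along(residues), function(i) {
    normalize_dna(residues[i], allow_gap = allow_gap,
                  what = paste0("sequence '", id[i], "'"))
  }, character(1))
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(id)),
             residues = residues,
             species = rep_len(as.character(species), length(id)),
             country = rep_len(as.character(country), length(id)),
             region_group = rep_len(as.character(region_group), length(id)),
             stringsAsFactors = FALSE)
}

#' Read a multi-record FASTA file into a panel
#'
#' Residues are upper-cased, 'U' is mapped to 'T', and descriptions (header
#' text after the first whitespace) are preserved. Illegal characters are
#' reported with the offending line number.
#'
#' @param path FASTA file.
#' @param allow_gap logical; permit '-' (aligned FASTA).
#' @return panel data.frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) {
    return(seq_panel(character(), character()))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- as.character(set)
  out <- tryCatch(
    seq_panel(id, res, description = desc, allow_gap = allow_gap),
    error = function(e) {
      stop(conditionMessage(e), locate_fasta_error(path, conditionMessage(e)),
           call. = FALSE)
    })
  out
}

# Best-effort line number for an illegal-character error message.
locate_fasta_error <- function(path, msg) {
  m <- regmatches(msg, regexec("sequence '([^']+)'.*character '(.)'", msg))[[1]]
  if (length(m) < 3) return("")
  lines <- readLines(path, warn = FALSE)
  hit <- grep(paste0("^>", m[2]), lines)[1]
  if (is.na(hit)) return("")
  for (i in seq(hit + 1L, length(lines))) {
    if (startsWith(lines[i], ">")) break
    if (grepl(m[3], toupper(lines[i]), fixed = TRUE)) {
      return(sprintf(" (file '%s', line %d)", path, i))
    }
  }
  ""
}

#' Write a panel to FASTA
#'
#' @param panel panel data.frame.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(panel, path) {
  headers <- ifelse(nzchar(panel$description) & !is.na(panel$description),
                    paste(panel$id, panel$description), panel$id)
  set <- Biostrings::BStringSet(panel$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read locally saved GenBank flat-file records
#'
#' Extracts ACCESSION (falling back to LOCUS) as the id, the ORGANISM line as
#' species, DEFINITION as the description, and the ORIGIN block (digits and
#' whitespace stripped) as residues. Supports multi-record files separated by
#' '//'. Intended for records saved from the NCBI Nucleotide database; no
#' network access is performed.
#'
#' @param path GenBank flat file.
#' @return panel data.frame with a species column filled in.
#' @export
read_genbank_flat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) }
  recs <- lapply(seq_along(starts), function(k) {
    chunk <- lines[starts[k]:ends[k]]
    if (!any(nzchar(trimws(chunk)))) return(NULL)
    acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
               grep("^ACCESSION", chunk, value = TRUE)[1])
    if (is.na(acc)) {
      acc <- sub("^LOCUS\\s+(\\S+).*$", "\\1",
                 grep("^LOCUS", chunk, value = TRUE)[1])
    }
    if (is.na(acc)) stop("GenBank record without ACCESSION/LOCUS in '",
                         path, "'", call. = FALSE)
    org <- grep("^\\s+ORGANISM", chunk, value = TRUE)[1]
    species <- if (is.na(org)) NA_character_ else
      trimws(sub("^\\s+ORGANISM\\s+", "", org))
    defn <- grep("^DEFINITION", chunk, value = TRUE)[1]
    description <- if (is.na(defn)) "" else
      trimws(sub("^DEFINITION\\s+", "", defn))
    oi <- grep("^ORIGIN", chunk)
    if (length(oi) == 0L) {
      stop("GenBank record '", acc, "' has no ORIGIN block", call. = FALSE)
    }
    seq_lines <- chunk[seq(oi[1] + 1L, length(chunk))]
    res <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))
    if (!nzchar(res)) {
      stop("GenBank record '", acc, "' has an empty ORIGIN block",
           call. = FALSE)
    }
    list(id = acc, description = description, residues = res,
         species = species)
  })
  recs <- Filter(Negate(is.null), recs)
  if (length(recs) == 0L) return(seq_panel(character(), character()))
  seq_panel(id = vapply(recs, `[[`, "", "id"),
            residues = vapply(recs, `[[`, "", "residues"),
            description = vapply(recs, `[[`, "", "description"),
            species = vapply(recs, `[[`, "", "species"))
}

#' Read a metadata TSV
#'
#' Expected columns: id, species, country, region_group, and optionally
#' haplotype_label. FASTA headers in public barcode dumps are too
#' inconsistent to parse reliably, so metadata travels in its own table
#' keyed by sequence id.
#'
#' @param path TSV file with a header row.
#' @return metadata data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "species", "country", "region_group")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$id)) {
    stop("metadata table has duplicate ids", call. = FALSE)
  }
  md
}

#' Attach metadata to a panel
#'
#' Panel ids that do not resolve in the metadata table keep NA metadata and
#' are listed in the "unresolved" attribute rather than dropped.
#'
#' @param panel panel data.frame.
#' @param metadata data.frame from \code{\link{read_metadata}}.
#' @return panel with species/country/region_group (and haplotype_label if
#'   present) filled in.
#' @export
attach_metadata <- function(panel, metadata) {
  i <- match(panel$id, metadata$id)
  for (col in intersect(c("species", "country", "region_group",
                          "haplotype_label"), names(metadata))) {
    panel[[col]] <- metadata[[col]][i]
  }
  attr(panel, "unresolved") <- panel$id[is.na(i)]
  panel
}

#' Reverse-complement an IUPAC DNA string
#'
#' Honors all IUPAC ambiguity codes (R to Y etc.) and alignment gaps; applying
#' it twice returns the input.
#'
#' @param s IUPAC DNA string.
#' @return reverse complement, same length.
#' @examples
#' reverse_complement("ACGT")   # palindrome
#' reverse_complement("AAAACC") # "GGTTTT"
#' @export
reverse_complement <- function(s) {
  s <- normalize_dna(s, allow_gap = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Complement of a vector of single IUPAC bases
#' @keywords internal
complement_base <- function(b) {
  out <- COMPLEMENT[b]
  if (anyNA(out)) stop("cannot complement base(s): ",
                       paste(unique(b[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}

# Does the template IUPAC code include this (unambiguous) primer base?
# Gaps, missing data ("") and anything non-IUPAC never match.
iupac_contains <- function(code, base) {
  if (!nzchar(code) || !code %in% IUPAC_LETTERS) return(FALSE)
  base %in% IUPAC_SETS[[code]]
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
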