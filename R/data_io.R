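# Readers and writers for interaction tables, proteome FASTA files and
# contact-map definitions.

.INTERACTION_COLS <- c("domain_id", "binding_site", "peptide", "label", "source")

#' Read a domain-peptide interaction table
#'
#' Reads a tab-delimited interaction table with header columns `domain_id`,
#' `binding_site`, `peptide`, `label` and `source` (an optional `organism`
#' column is carried through to the domain table). Each row pairs a PDZ
#' domain, represented by its aligned 16-residue binding-site sequence, with
#' a 5-residue C-terminal peptide and a binary label (+1 binder, -1
#' non-binder). Duplicate (domain, peptide, label) rows are dropped with a
#' warning.
#'
#' @param path path to a UTF-8, tab-delimited file with a header row.
#' @param format input format; only `"tsv"` is supported.
#' @return a \code{\linkS4class{PdzInteractionSet}}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("domain_id\tbinding_site\tpeptide\tlabel\tsource",
#'              "D1\tAAAAAAAAAAAAAAAA\tETWVF\t1\tdemo"), tsv)
#' readInteractions(tsv)
#' @export
readInteractions <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  missing <- setdiff(.INTERACTION_COLS, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(tab)
  tab$domain_id <- as.character(tab$domain_id)
  tab$binding_site <- as.character(tab$binding_site)
  tab$peptide <- as.character(tab$peptide)
  tab$source <- as.character(tab$source)
  lab <- suppressWarnings(as.integer(tab$label))
  # Row numbers reported to the user count the header as line 1.
  for (i in seq_len(n)) {
    if (is.na(lab[i]) || !(lab[i] %in% c(-1L, 1L)))
      stop("line ", i + 1L, ": label must be +1 or -1, got '", tab$label[i], "'")
    if (!.isValidPeptide(tab$peptide[i]))
      stop("line ", i + 1L, ": invalid peptide '", tab$peptide[i],
           "' (need 5 standard residues, no gaps)")
    if (!.isValidSite(tab$binding_site[i]))
      stop("line ", i + 1L, ": invalid binding site '", tab$binding_site[i],
           "' (need 16 characters over the amino-acid alphabet plus '-')")
  }
  tab$label <- lab
  dup <- duplicated(tab[, c("domain_id", "peptide", "label")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (domain, peptide, label) row(s) removed")
    tab <- tab[!dup, , drop = FALSE]
  }
  organism <- if ("organism" %in% names(tab)) as.character(tab$organism) else
    rep("unknown", nrow(tab))
  firsts <- !duplicated(tab$domain_id)
  dom <- data.frame(id = tab$domain_id[firsts],
                    organism = organism[firsts],
                    binding_site = tab$binding_site[firsts],
                    source = tab$source[firsts],
                    stringsAsFactors = FALSE)
  # A domain id must map to a single binding site.
  bad <- vapply(split(tab$binding_site, tab$domain_id),
                function(v) length(unique(v)) > 1L, logical(1))
  if (any(bad))
    stop("domain '", names(bad)[bad][1], "' has conflicting binding sites")
  it <- data.frame(domain_id = tab$domain_id, peptide = tab$peptide,
                   label = tab$label, source = tab$source,
                   stringsAsFactors = FALSE)
  rownames(it) <- NULL; rownames(dom) <- NULL
  methods::new("PdzInteractionSet", interactions = it, domains = dom)
}

#' Write a PdzInteractionSet to a tab-delimited file
#'
#' Inverse of [readInteractions()]: writes the canonical five-column table
#' (plus `organism`), one interaction per row.
#'
#' @param x a \code{\linkS4class{PdzInteractionSet}}.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeInteractions <- function(x, path) {
  stopifnot(is(x, "PdzInteractionSet"))
  it <- x@interactions
  dm <- x@domains
  idx <- match(it$domain_id, dm$id)
  out <- data.frame(domain_id = it$domain_id,
                    binding_site = dm$binding_site[idx],
                    peptide = it$peptide,
                    label = it$label,
                    source = it$source,
                    organism = dm$organism[idx],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract unique C-terminal tails from a proteome
#'
#' Reads protein sequences from a FASTA file and collects the last `k`
#' residues of every sequence, after stripping any trailing stop character
#' `'*'`. The result maps each unique tail to the ids of all proteins that
#' end with it, which is the scanning universe used throughout the package
#' (the original human scan covered 41,193 unique 5-residue tails).
#'
#' @param proteome path to a protein FASTA file, or a named character vector
#'   of sequences (names are protein ids).
#' @param k tail length; default 5.
#' @return named list mapping each unique k-mer tail to a character vector of
#'   protein ids. Sequences shorter than `k` are skipped with a warning.
#' @export
extractCTerminalTails <- function(proteome, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    aa <- Biostrings::readAAStringSet(proteome)
    seqs <- as.character(aa)
    names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  } else if (is.character(proteome)) {
    seqs <- proteome
    if (is.null(names(seqs)) && length(seqs))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("proteome must be a FASTA path or a named character vector")
  }
  if (length(seqs) == 0L) {
    warning("empty proteome: no tails extracted")
    return(structure(list(), names = character(0)))
  }
  seqs <- sub("\\*+$", "", seqs)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k, " skipped")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0L) return(structure(list(), names = character(0)))
  tails <- substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))
  split(names(seqs), tails)
}

.parsePepPos <- function(tok) {
  tok <- sub("^p", "", tok)
  suppressWarnings(as.integer(tok))
}

#' Load a contact-map definition
#'
#' Reads a whitespace-delimited file with one contacting position pair per
#' line: a domain binding-site position (1..16) and a peptide position
#' (written either as an integer -4..0 or as p-4..p0). Lines starting with
#' `#` are comments.
#'
#' @param path path to the definition file.
#' @return a validated \code{\linkS4class{ContactMap}}.
#' @seealso [defaultContactMap()] for the shipped 38-pair default.
#' @export
loadContactMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("contact map file has no pairs")
  toks <- strsplit(ln, "[[:space:]]+")
  if (any(lengths(toks) != 2L))
    stop("each line must contain exactly two fields: domain_pos peptide_pos")
  dpos <- suppressWarnings(as.integer(vapply(toks, `[`, character(1), 1L)))
  ppos <- .parsePepPos(vapply(toks, `[`, character(1), 2L))
  if (anyNA(dpos) || anyNA(ppos)) stop("unparseable position in contact map")
  if (!all(dpos %in% seq_len(.SITE_LEN)))
    stop("domain position out of range 1..16: ", dpos[!dpos %in% seq_len(.SITE_LEN)][1])
  if (!all(ppos %in% .PEP_POS))
    stop("peptide position out of range p-4..p0: ", ppos[!ppos %in% .PEP_POS][1])
  pairs <- data.frame(domain_pos = dpos, peptide_pos = ppos)
  if (anyDuplicated(pairs)) stop("duplicate contact pair in file")
  methods::new("ContactMap", pairs = pairs)
}

#' The default 38-pair contact map
#'
#' Returns the contact map shipped with the package: 38 (domain position,
#' peptide position) pairs covering all 16 binding-site positions and all 5
#' peptide positions, matching the structural constants of the alpha1-
#' syntrophin-derived map (16 domain positions within 5 A of the last five
#' peptide residues; 38 contacting pairs). The identity of the individual
#' pairs is a synthetic reconstruction -- the encoding depends only on the
#' pair count and coverage, which are exact.
#'
#' @return a \code{\linkS4class{ContactMap}} with 38 pairs.
#' @export
defaultContactMap <- function() {
  loadContactMap(system.file("extdata", "contact_map_default.txt",
                             package = "pdzscan", mustWork = TRUE))
}

#' Write predictions to a tab-delimited file
#'
#' @param x a \code{\linkS4class{ScanResult}}.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
writeScanResult <- function(x, path) {
  stopifnot(is(x, "ScanResult"))
  out <- x@predictions
  out <- cbind(domain_id = x@domainId, out, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
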