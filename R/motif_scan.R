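# Match-style PWM promoter scanning. A position weight matrix is scored
# against a window with the information-weighted similarity
#   score = (Current - Min) / (Max - Min),
#   Current = sum_i I(i) * f(i, b_i),
# where f are pseudocount-smoothed column frequencies, I(i) is the column
# information weight, and Min/Max are the analogous sums over the
# per-position minimum/maximum frequencies. The core score applies the same
# formula restricted to the 5 consecutive most informative positions.

BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' @param name TF identifier.
#' @param counts numeric matrix of nonnegative base counts, rows A/C/G/T,
#'   columns positions.
#' @param pseudocount smoothing mass added to every normalised column
#'   frequency before renormalisation (default 0.25), so scores are
#'   invariant to rescaling all counts by a positive constant.
#' @return An object of class `pwm` with elements `name`, `counts`, `freq`,
#'   `information` (per-position weight I(i) = sum_b f ln(4 f)),
#'   `core_positions` (the 5 consecutive positions of maximal summed
#'   information, leftmost on ties), `length`.
#' @export
pwm <- function(name, counts, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A,C,G,T)", call. = FALSE)
  rownames(counts) <- BASES
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM counts must be finite and nonnegative", call. = FALSE)
  if (any(colSums(counts) <= 0)) stop("every PWM column must have positive sum", call. = FALSE)
  p <- sweep(counts, 2L, colSums(counts), "/")
  freq <- (p + pseudocount) / (1 + 4 * pseudocount)
  info <- colSums(freq * log(4 * freq))
  L <- ncol(counts)
  core_len <- min(5L, L)
  sums <- vapply(seq_len(L - core_len + 1L),
                 function(s) sum(info[s:(s + core_len - 1L)]), numeric(1))
  s0 <- which.max(sums)  # which.max takes the leftmost maximum
  structure(list(name = name, counts = counts, freq = freq, information = info,
                 core_positions = s0:(s0 + core_len - 1L), length = L,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, core %d-%d\n", x$name, x$length,
              min(x$core_positions), max(x$core_positions)))
  invisible(x)
}

#' Read PWMs from a TRANSFAC-dialect flat file
#'
#' Parses the classic `ID` / `P0` / numbered-row layout: each matrix starts
#' at an `ID` line, the `P0` line gives the column order (A C G T), numbered
#' rows give per-position counts, and `//` terminates the record. `NA`-named
#' matrices are rejected.
#'
#' @param path flat-file path.
#' @param pseudocount see [pwm()].
#' @return list of [pwm()] objects.
#' @export
read_transfac <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  name <- NULL; rows <- list(); order_ <- BASES
  flush <- function() {
    if (!is.null(name) && length(rows)) {
      m <- do.call(cbind, rows)  # columns = positions
      rownames(m) <- order_
      out[[length(out) + 1L]] <<- pwm(name, m[BASES, , drop = FALSE], pseudocount)
    }
    name <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "ID")) { flush(); name <- trimws(sub("^ID\\s+", "", ln)) }
    else if (startsWith(ln, "P0")) {
      order_ <- strsplit(trimws(sub("^P0\\s+", "", ln)), "\\s+")[[1L]][1:4]
    } else if (grepl("^[0-9]+\\s", ln)) {
      v <- strsplit(trimws(ln), "\\s+")[[1L]]
      rows[[length(rows) + 1L]] <- as.numeric(v[2:5])
    } else if (startsWith(ln, "//")) flush()
  }
  flush()
  if (length(out) == 0L) stop("no matrices parsed from ", path, call. = FALSE)
  out
}

#' Consensus sequence of a PWM (per-position argmax base)
#' @param x a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$freq, 2L, which.max)], collapse = "")
}

#' Core and matrix similarity scores of one window
#'
#' @param pwm a [pwm()].
#' @param window nucleotide string of exactly the matrix length, with no N.
#' @return named numeric vector `c(core_score=, matrix_score=)`, both in
#'   \[0, 1\].
#' @export
similarity_scores <- function(pwm, window) {
  b <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(b) != pwm$length)
    stop("window length ", length(b), " != matrix length ", pwm$length, call. = FALSE)
  idx <- match(b, BASES)
  if (anyNA(idx)) stop("window contains non-ACGT characters", call. = FALSE)
  score_on <- function(pos) {
    f <- pwm$freq[, pos, drop = FALSE]
    I <- pwm$information[pos]
    cur <- sum(I * f[cbind(idx[pos], seq_along(pos))])
    mn <- sum(I * apply(f, 2L, min))
    mx <- sum(I * apply(f, 2L, max))
    if (mx == mn) return(1)  # fully uninformative matrix: every window is a perfect match
    (cur - mn) / (mx - mn)
  }
  c(core_score = score_on(pwm$core_positions),
    matrix_score = score_on(seq_len(pwm$length)))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

scan_one_strand <- function(pwm, seq_chars, strand, core_cutoff, matrix_cutoff) {
  L <- pwm$length
  n <- length(seq_chars)
  if (n < L) return(NULL)
  idx <- match(seq_chars, BASES)  # N and others become NA -> window skipped
  I <- pwm$information
  fmin <- apply(pwm$freq, 2L, min)
  fmax <- apply(pwm$freq, 2L, max)
  mn_all <- sum(I * fmin); mx_all <- sum(I * fmax)
  core <- pwm$core_positions
  mn_core <- sum(I[core] * fmin[core]); mx_core <- sum(I[core] * fmax[core])
  # per-position weighted frequency of each observed base, then rolling sums
  wf <- matrix(NA_real_, nrow = n, ncol = L)
  for (p in seq_len(L)) {
    ok <- !is.na(idx)
    wf[ok, p] <- I[p] * pwm$freq[cbind(idx[ok], p)]
  }
  starts <- seq_len(n - L + 1L)
  cur_all <- rep(0, length(starts))   # NA from an N in the window propagates
  cur_core <- rep(0, length(starts))
  for (p in seq_len(L)) {
    contrib <- wf[starts + p - 1L, p]
    cur_all <- cur_all + contrib
    if (p %in% core) cur_core <- cur_core + contrib
  }
  ms <- if (mx_all > mn_all) (cur_all - mn_all) / (mx_all - mn_all) else rep(1, length(starts))
  cs <- if (mx_core > mn_core) (cur_core - mn_core) / (mx_core - mn_core) else rep(1, length(starts))
  keep <- !is.na(ms) & !is.na(cs) & cs >= core_cutoff & ms >= matrix_cutoff
  if (!any(keep)) return(NULL)
  data.frame(position = starts[keep] - 1L, strand = strand,
             core_score = cs[keep], matrix_score = ms[keep],
             stringsAsFactors = FALSE)
}

#' Promoter record
#'
#' @param node gene or miRNA identifier the promoter belongs to.
#' @param species species code.
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param window integer pair `(upstream_bp, downstream_bp)` relative to the
#'   TSS; default `c(1500, 500)`.
#' @return object of class `promoter_record`.
#' @export
promoter_record <- function(node, species, sequence, window = c(1500, 500)) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("promoter sequence contains characters outside A/C/G/T/N", call. = FALSE)
  structure(list(node = node, species = species, sequence = sequence,
                 window = as.integer(window)),
            class = "promoter_record")
}

#' Read promoters from FASTA with `nodeID|species|window` headers
#'
#' The header encodes the owning node, species code, and promoter window as
#' `nodeID|species|-1500/+500`.
#'
#' @param path FASTA file path.
#' @return list of [promoter_record()] objects.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    parts <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("promoter FASTA header must be 'nodeID|species|window': ", names(seqs)[i],
           call. = FALSE)
    win <- as.integer(strsplit(gsub("[+]", "", parts[3L]), "/", fixed = TRUE)[[1L]])
    promoter_record(parts[1L], parts[2L], as.character(seqs[[i]]), abs(win))
  })
}

#' Write promoters to FASTA
#' @param promoters list of [promoter_record()].
#' @param path output path.
#' @export
write_promoters <- function(promoters, path) {
  lines <- unlist(lapply(promoters, function(p) {
    c(sprintf(">%s|%s|-%d/+%d", p$node, p$species, p$window[1L], p$window[2L]),
      p$sequence)
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Scan promoter windows with a set of PWMs
#'
#' Slides every matrix over every promoter on both strands and reports the
#' windows meeting both score cutoffs. Windows containing N are skipped;
#' reverse-strand hits are scored on the reverse complement and reported at
#' the forward-strand offset of the window start.
#'
#' @param pwms list of [pwm()] objects.
#' @param promoters list of [promoter_record()] objects.
#' @param core_cutoff,matrix_cutoff score cutoffs in \[0, 1\]; defaults 1.00
#'   and 0.95.
#' @return data frame of hits: `tf`, `node`, `species`, `position` (0-based
#'   offset of the window start on the given strand's reported coordinate),
#'   `strand`, `core_score`, `matrix_score`.
#' @export
scan_promoters <- function(pwms, promoters, core_cutoff = 1.00, matrix_cutoff = 0.95) {
  stopifnot(core_cutoff >= 0, core_cutoff <= 1, matrix_cutoff >= 0, matrix_cutoff <= 1)
  out <- list()
  for (p in promoters) {
    fwd <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    rev_ <- strsplit(reverse_complement(p$sequence), "", fixed = TRUE)[[1L]]
    for (m in pwms) {
      hf <- scan_one_strand(m, fwd, "+", core_cutoff, matrix_cutoff)
      hr <- scan_one_strand(m, rev_, "-", core_cutoff, matrix_cutoff)
      if (!is.null(hr)) # report reverse hits at forward coordinates of the window start
        hr$position <- nchar(p$sequence) - m$length - hr$position
      h <- rbind(hf, hr)
      if (!is.null(h) && nrow(h)) {
        h$tf <- m$name; h$node <- p$node; h$species <- p$species
        out[[length(out) + 1L]] <- h[, c("tf", "node", "species", "position",
                                         "strand", "core_score", "matrix_score")]
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(tf = character(0), node = character(0), species = character(0),
                      position = integer(0), strand = character(0),
                      core_score = numeric(0), matrix_score = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$tf, res$node, res$species, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Cross-species conserved TF edges from motif hits
#'
#' Emits a TF-gene or TF-miRNA edge for each (TF, node) pair with at least
#' one motif hit in every required species; hit positions need not align
#' across species.
#'
#' @param hits_by_species named list (species code -> hit data frame as
#'   returned by [scan_promoters()]).
#' @param catalog a [node_catalog()].
#' @param required_species species codes that must all contain a hit.
#' @return An [edge_store()].
#' @export
conserved_tf_edges <- function(hits_by_species, catalog,
                               required_species = c("hsa", "mmu", "rno")) {
  if (length(required_species) == 0L)
    stop("required_species must be non-empty", call. = FALSE)
  miss <- setdiff(required_species, names(hits_by_species))
  if (length(miss))
    stop("no hits supplied for required species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pair_sets <- lapply(required_species, function(sp) {
    h <- hits_by_species[[sp]]
    unique(paste(h$tf, h$node, sep = "\r"))
  })
  conserved <- Reduce(intersect, pair_sets)
  if (length(conserved) == 0L) return(edge_store(NULL, catalog))
  parts <- do.call(rbind, strsplit(conserved, "\r", fixed = TRUE))
  tf <- parts[, 1L]; node <- parts[, 2L]
  as_gene <- in_class(catalog, node, "gene")
  as_mirna <- in_class(catalog, node, "mirna")
  edges <- rbind(
    if (any(as_gene)) data.frame(source = tf[as_gene], target = node[as_gene],
                                 relation = "TF-gene", score = NA_real_),
    if (any(as_mirna)) data.frame(source = tf[as_mirna], target = node[as_mirna],
                                  relation = "TF-miRNA", score = NA_real_))
  edge_store(edges, catalog)
}
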