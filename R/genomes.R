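#' ffdcj: family-free DCJ distance and similarity
#'
#' Tools for comparing two genomes under the double-cut-and-join (DCJ)
#' rearrangement model when no gene family assignment is available.
#' Genomes are signed gene orders over linear and/or circular chromosomes;
#' the only other input is a table of pairwise normalized gene similarities
#' sigma in (0, 1]. The package covers the classical family-based DCJ
#' distance (adjacency graph, component census, n - c - i/2), the
#' family-free distance d_sigma and similarity s_sigma of reduced genomes
#' under a matching of the gene similarity graph, exact optimization over
#' maximal matchings (brute-force enumeration and a branch-and-bound
#' solver for the integer linear programming formulation), hardness-gadget
#' generators, a small rearrangement simulator, and a command-line
#' interface.
#'
#' @keywords internal
"_PACKAGE"

GENE_TOKEN_RX <- "^[A-Za-z0-9_.]+$"

#' Construct a chromosome
#'
#' A chromosome is an oriented sequence of signed genes, either linear or
#' circular.
#'
#' @param tokens character vector of signed gene tokens, e.g.
#'   `c("-1", "3", "4", "2")`; a leading `-` marks reverse orientation.
#'   Gene names match `[A-Za-z0-9_.]+`.
#' @param circular logical; `TRUE` for a circular chromosome.
#' @return An object of class `"chromosome"`: a list with character
#'   `genes`, integer `signs` (+1/-1) and logical `circular`.
#' @examples
#' chromosome(c("3", "-1", "4", "2"))
#' chromosome("5", circular = TRUE)
#' @export
chromosome <- function(tokens, circular = FALSE) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) stop("empty chromosome", call. = FALSE)
  neg <- startsWith(tokens, "-")
  nm <- sub("^-", "", tokens)
  bad <- !grepl(GENE_TOKEN_RX, nm)
  if (any(bad)) {
    stop("malformed gene token: '", tokens[bad][1L], "'", call. = FALSE)
  }
  structure(list(genes = nm,
                 signs = ifelse(neg, -1L, 1L),
                 circular = isTRUE(circular)),
            class = "chromosome")
}

#' Construct a genome
#'
#' @param name genome name (a token without whitespace).
#' @param chromosomes a list of [chromosome()] objects, or a single
#'   chromosome.
#' @return An object of class `"genome"`.
#' @examples
#' genome("A", chromosome(c("-1", "3", "4", "2")))
#' @export
genome <- function(name, chromosomes = list()) {
  if (inherits(chromosomes, "chromosome")) chromosomes <- list(chromosomes)
  stopifnot(is.list(chromosomes),
            all(vapply(chromosomes, inherits, logical(1), "chromosome")))
  name <- as.character(name)
  if (length(name) != 1L || is.na(name) || !nzchar(name) || grepl("\\s", name)) {
    stop("genome name must be a non-empty token", call. = FALSE)
  }
  structure(list(name = name, chromosomes = chromosomes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("Genome", x$name, "-", length(x$chromosomes), "chromosome(s),",
      n_genes(x), "gene(s)\n")
  for (ch in x$chromosomes) {
    cat(" ", paste(chromosome_tokens(ch), collapse = " "),
        if (ch$circular) ")" else "|", "\n")
  }
  invisible(x)
}

chromosome_tokens <- function(ch) {
  paste0(ifelse(ch$signs < 0L, "-", ""), ch$genes)
}

#' Gene content of a genome
#'
#' `gene_set()` returns the set of distinct gene names; `n_genes()` the
#' total number of gene occurrences (equal to the set size when the genome
#' is duplication-free); `gene_occurrences()` each occurrence in
#' chromosome order.
#'
#' @param G a [genome()].
#' @return `gene_set()`: character vector; `n_genes()`: integer;
#'   `gene_occurrences()`: data.frame with columns `gene`, `sign`,
#'   `chromosome`, `position`.
#' @export
gene_set <- function(G) {
  unique(unlist(lapply(G$chromosomes, `[[`, "genes"), use.names = FALSE))
}

#' @rdname gene_set
#' @export
n_genes <- function(G) {
  sum(vapply(G$chromosomes, function(ch) length(ch$genes), integer(1)))
}

#' @rdname gene_set
#' @export
gene_occurrences <- function(G) {
  out <- lapply(seq_along(G$chromosomes), function(i) {
    ch <- G$chromosomes[[i]]
    data.frame(gene = ch$genes, sign = ch$signs, chromosome = i,
               position = seq_along(ch$genes))
  })
  if (length(out) == 0L) {
    return(data.frame(gene = character(), sign = integer(),
                      chromosome = integer(), position = integer()))
  }
  do.call(rbind, out)
}

validate_genome <- function(G, allow_duplicates = FALSE) {
  stopifnot(inherits(G, "genome"))
  occ <- gene_occurrences(G)
  if (!allow_duplicates && anyDuplicated(occ$gene)) {
    dup <- occ$gene[duplicated(occ$gene)][1L]
    stop("duplicate gene '", dup, "' in genome ", G$name, call. = FALSE)
  }
  invisible(G)
}

#' Parse genomes from UniMoG-style text
#'
#' The dialect: a header line `>name` opens a genome; chromosomes are
#' whitespace-separated signed gene tokens terminated by `|` (linear) or
#' `)` (circular); `#` starts a comment running to end of line.
#' Chromosomes may span lines; a chromosome must be terminated before the
#' next header or end of input.
#'
#' @param text a character vector of lines, a single string, or a file
#'   path (a path is detected when the value has no newline and names an
#'   existing file). Use `"-"` for standard input.
#' @return A list of [genome()] objects, named by genome name.
#' @examples
#' gs <- parse_genomes(">A\n-1 3 4 2 |\n>B\n-2 1 4 3 |")
#' gs$A
#' @export
parse_genomes <- function(text) {
  lines <- read_input_lines(text)
  lines <- sub("#.*$", "", lines)
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  cur_tokens <- character()

  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_tokens) > 0L) {
      stop("unterminated chromosome in genome '", cur_name, "'",
           call. = FALSE)
    }
    if (!is.null(genomes[[cur_name]])) {
      stop("duplicate genome name '", cur_name, "'", call. = FALSE)
    }
    genomes[[cur_name]] <<- genome(cur_name, cur_chroms)
  }

  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(substring(line, 2L))
      if (!nzchar(cur_name)) stop("empty genome name", call. = FALSE)
      cur_chroms <- list()
      cur_tokens <- character()
      next
    }
    if (is.null(cur_name)) {
      stop("gene data before any genome header", call. = FALSE)
    }
    for (tok in strsplit(line, "\\s+")[[1L]]) {
      if (tok %in% c("|", ")")) {
        if (length(cur_tokens) == 0L) {
          stop("empty chromosome in genome '", cur_name, "'", call. = FALSE)
        }
        cur_chroms[[length(cur_chroms) + 1L]] <-
          chromosome(cur_tokens, circular = (tok == ")"))
        cur_tokens <- character()
      } else {
        cur_tokens <- c(cur_tokens, tok)
      }
    }
  }
  flush_genome()
  if (length(genomes) == 0L) stop("no genome header found", call. = FALSE)
  genomes
}

read_input_lines <- function(text) {
  if (length(text) == 1L && !is.na(text)) {
    if (identical(text, "-")) return(readLines("stdin"))
    if (!grepl("\n", text) && file.exists(text)) return(readLines(text))
  }
  unlist(strsplit(as.character(text), "\n", fixed = TRUE), use.names = FALSE)
}

#' Serialize genomes to UniMoG-style text
#'
#' Inverse of [parse_genomes()]: `parse_genomes(write_genomes(G))` is
#' canonically equal to `G`.
#'
#' @param genomes a list of [genome()] objects (or a single genome).
#' @param path optional file path; when given, the text is written there.
#' @return The document as a single character string (invisibly when
#'   `path` is given).
#' @export
write_genomes <- function(genomes, path = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  stopifnot(length(genomes) > 0L)
  out <- character()
  for (G in genomes) {
    stopifnot(inherits(G, "genome"))
    if (length(G$chromosomes) == 0L) {
      stop("genome '", G$name, "' has no chromosomes", call. = FALSE)
    }
    out <- c(out, paste0(">", G$name))
    for (ch in G$chromosomes) {
      out <- c(out, paste(c(chromosome_tokens(ch),
                            if (ch$circular) ")" else "|"),
                          collapse = " "))
    }
  }
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(doc))
  }
  doc
}

extremity <- function(gene, side) paste0(gene, ":", side)

# Leading/trailing extremity of each gene as laid along the chromosome:
# a forward gene is entered at its tail and left at its head.
chromosome_extremities <- function(ch) {
  list(lead  = extremity(ch$genes, ifelse(ch$signs > 0L, "t", "h")),
       trail = extremity(ch$genes, ifelse(ch$signs > 0L, "h", "t")))
}

#' Adjacencies of a genome
#'
#' An adjacency is either a pair of consecutive gene extremities or, at
#' the end of a linear chromosome, a single telomeric extremity. A linear
#' chromosome of m genes yields m + 1 adjacencies (two telomeric); a
#' circular chromosome of m genes yields m adjacencies.
#'
#' @param G a duplication-free [genome()].
#' @return A list of adjacencies; each is a character vector of one or two
#'   extremity labels `"gene:t"` / `"gene:h"` (pairs sorted).
#' @examples
#' genome_adjacencies(genome("A", chromosome(c("3", "-1", "4", "2"))))
#' @export
genome_adjacencies <- function(G) {
  validate_genome(G)
  adjs <- list()
  for (ch in G$chromosomes) {
    e <- chromosome_extremities(ch)
    m <- length(ch$genes)
    if (ch$circular) {
      for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        adjs[[length(adjs) + 1L]] <- sort(c(e$trail[i], e$lead[j]))
      }
    } else {
      adjs[[length(adjs) + 1L]] <- e$lead[1L]
      if (m > 1L) {
        for (i in seq_len(m - 1L)) {
          adjs[[length(adjs) + 1L]] <- sort(c(e$trail[i], e$lead[i + 1L]))
        }
      }
      adjs[[length(adjs) + 1L]] <- e$trail[m]
    }
  }
  adjs
}

canonical_chromosome <- function(ch) {
  fwd <- chromosome_tokens(ch)
  rev_ <- rev(paste0(ifelse(ch$signs < 0L, "", "-"), ch$genes))
  if (!ch$circular) {
    cands <- list(fwd, rev_)
  } else {
    m <- length(fwd)
    rot <- function(v) lapply(seq_len(m), function(k) {
      if (k == 1L) v else c(v[k:m], v[1:(k - 1L)])
    })
    cands <- c(rot(fwd), rot(rev_))
  }
  keys <- vapply(cands, paste, character(1), collapse = " ")
  best <- cands[[which.min(rank(keys, ties.method = "first"))]]
  chromosome(best, circular = ch$circular)
}

#' Canonical form of a genome
#'
#' Maps a genome to a unique representative: a linear chromosome and its
#' full reversal (order reversed, signs flipped) are identified; a
#' circular chromosome is invariant under rotation and reversal;
#' chromosomes are sorted by their canonical serialization. Idempotent.
#' Useful for comparing genomes for equality.
#'
#' @param G a [genome()].
#' @return A [genome()] in canonical form.
#' @export
canonicalize <- function(G) {
  stopifnot(inherits(G, "genome"))
  chroms <- lapply(G$chromosomes, canonical_chromosome)
  keys <- vapply(chroms, function(ch) {
    paste(c(chromosome_tokens(ch), if (ch$circular) ")" else "|"),
          collapse = " ")
  }, character(1))
  genome(G$name, chroms[order(keys, method = "radix")])
}

#' Test two genomes for canonical equality
#'
#' @param A,B [genome()] objects.
#' @return `TRUE` iff `A` and `B` have the same chromosomes up to
#'   reversal, rotation (circular) and chromosome order; names ignored.
#' @export
genomes_equal <- function(A, B) {
  a <- canonicalize(A)
  b <- canonicalize(B)
  ser <- function(G) vapply(G$chromosomes, function(ch) {
    paste(c(chromosome_tokens(ch), if (ch$circular) ")" else "|"),
          collapse = " ")
  }, character(1))
  identical(ser(a), ser(b))
}
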