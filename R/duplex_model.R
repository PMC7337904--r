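## duplex_model: base pairing into an antiparallel duplex and IUPAC
## recognition-site annotation.
##
## A `duplex` is a list with
##   pairs   data.frame: pos, i_uid, j_uid, base_i, base_j, pair_type
##           (ordered 5'->3' along the reference strand; i is the reference
##           strand residue, j its partner)
##   model   the structure_model the pairs refer to
##   site_span   integer c(from, to) into pairs, or NULL
##   site_pattern IUPAC string or NA

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

iupac_match_base <- function(code, base) {
  allowed <- IUPAC_CODES[[toupper(code)]]
  if (is.null(allowed)) stop("illegal IUPAC character: ", code)
  b <- toupper(base)
  if (b == "U") b <- "T"
  b %in% allowed
}

## all window start positions where pattern matches seq (character vectors)
iupac_find <- function(seq_letters, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(pat, names(IUPAC_CODES))
  if (length(bad)) stop("illegal IUPAC character(s): ", paste(bad, collapse = ""))
  n <- length(seq_letters); m <- length(pat)
  if (m > n) return(integer())
  hits <- integer()
  for (s in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!iupac_match_base(pat[k], seq_letters[s + k - 1L])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

residue_atoms <- function(model, uid) {
  model$atoms[model$atoms$res_uid == uid, , drop = FALSE]
}

residue_atom_xyz <- function(model, uid, name) {
  a <- residue_atoms(model, uid)
  i <- match(name, normalize_atom_name(a$atom))
  if (is.na(i)) return(NULL)
  as.numeric(a[i, c("x", "y", "z")])
}

#' Pair bases into an antiparallel duplex
#'
#' Finds Watson-Crick pairs between nucleotide residues using three
#' criteria: C1'-C1' distance 10.4 +/- 1.5 Angstrom, at least one canonical
#' WC donor-acceptor distance below 3.5 Angstrom, and anti-aligned base
#' normals (z-axis dot product < -0.5).  Each nucleotide enters at most one
#' pair; pairs are returned ordered 5'->3' along the reference strand.
#'
#' @param model a `structure_model` with at least two nucleotides.
#' @param chain_pair optional character(2): restrict pairing to these chains.
#' @return a `duplex`.
#' @export
pair_bases <- function(model, chain_pair = NULL) {
  at <- model$atoms
  nt_uid <- unique(at$res_uid[at$category %in% c("DNA", "RNA")])
  if (!is.null(chain_pair)) {
    keep <- at$chain[match(nt_uid, at$res_uid)] %in% chain_pair
    nt_uid <- nt_uid[keep]
  }
  if (length(nt_uid) < 2L) stop("empty duplex: fewer than 2 nucleotides")
  info <- lapply(nt_uid, function(u) {
    res <- residue_atoms(model, u)
    b <- base_letter(res$resid[1L])
    fr <- tryCatch(fit_base_frame(res), error = function(e) NULL)
    c1 <- residue_atom_xyz(model, u, "C1'")
    list(uid = u, base = b, frame = fr, c1 = c1, chain = res$chain[1L],
         res = res)
  })
  names(info) <- as.character(nt_uid)
  usable <- vapply(info, function(z) {
    !is.na(z$base) && !is.null(z$frame) && !is.null(z$c1)
  }, logical(1L))
  info <- info[usable]
  if (length(info) < 2L) stop("empty duplex: no pairable nucleotides")
  ## candidate pairs
  cand <- list()
  uids <- names(info)
  for (a in seq_along(info)) {
    for (b in seq_along(info)) {
      if (b <= a) next
      ia <- info[[a]]; ib <- info[[b]]
      d_c1 <- vnorm(ia$c1 - ib$c1)
      if (d_c1 < 8.9 || d_c1 > 11.9) next
      if (sum(ia$frame$axes[, 3L] * ib$frame$axes[, 3L]) >= -0.5) next
      ## coplanarity: within a WC pair the two base-frame origins nearly
      ## coincide (both sit at the pair center); neighbors are a rise apart
      d_org <- vnorm(ia$frame$origin - ib$frame$origin)
      if (d_org > 2.5) next
      hb <- wc_hbond_atoms(ia$base, ib$base)
      if (is.null(hb)) next
      dmin <- Inf
      for (pr in hb) {
        p1 <- residue_atom_xyz(model, ia$uid, pr[1L])
        p2 <- residue_atom_xyz(model, ib$uid, pr[2L])
        if (!is.null(p1) && !is.null(p2)) dmin <- min(dmin, vnorm(p1 - p2))
      }
      if (!is.finite(dmin) || dmin >= 3.5) next
      cand[[length(cand) + 1L]] <- list(a = uids[a], b = uids[b],
                                        hb = d_org + dmin)
    }
  }
  if (!length(cand)) stop("empty duplex: no base pairs found")
  ## greedy one-pair-per-nucleotide assignment, best hydrogen bonds first
  ord <- order(vapply(cand, `[[`, numeric(1L), "hb"))
  used <- character(); pairs <- list()
  for (k in ord) {
    p <- cand[[k]]
    if (p$a %in% used || p$b %in% used) next
    used <- c(used, p$a, p$b)
    pairs[[length(pairs) + 1L]] <- p
  }
  ## reference strand: the chain contributing most first members
  ch_a <- vapply(pairs, function(p) info[[p$a]]$chain, character(1L))
  ch_b <- vapply(pairs, function(p) info[[p$b]]$chain, character(1L))
  ref_chain <- names(sort(table(c(ch_a, ch_b)), decreasing = TRUE))[1L]
  pr <- do.call(rbind, lapply(pairs, function(p) {
    ia <- info[[p$a]]; ib <- info[[p$b]]
    if (ib$chain == ref_chain && ia$chain != ref_chain) { tmp <- ia; ia <- ib; ib <- tmp }
    data.frame(i_uid = ia$uid, j_uid = ib$uid, base_i = ia$base,
               base_j = ib$base, pair_type = "WC", stringsAsFactors = FALSE)
  }))
  ## order along the reference strand (file order of residues within chain)
  ord2 <- order(pr$i_uid)
  pr <- pr[ord2, , drop = FALSE]
  pr$pos <- seq_len(nrow(pr))
  rownames(pr) <- NULL
  structure(list(pairs = pr[, c("pos", "i_uid", "j_uid", "base_i", "base_j",
                                "pair_type")],
                 model = model, site_span = NULL,
                 site_pattern = NA_character_),
            class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  cat("<duplex> ", nrow(x$pairs), " base pairs: 5'-",
      paste(x$pairs$base_i, collapse = ""), "-3'\n", sep = "")
  if (!is.null(x$site_span)) {
    cat("  site ", x$site_pattern, " at positions ",
        x$site_span[1L], "-", x$site_span[2L], "\n", sep = "")
  }
  invisible(x)
}

## reverse the duplex: swap strands so the old partner strand becomes the
## reference strand read 5'->3'
reverse_duplex <- function(duplex) {
  pr <- duplex$pairs[rev(seq_len(nrow(duplex$pairs))), , drop = FALSE]
  pr <- data.frame(pos = seq_len(nrow(pr)), i_uid = pr$j_uid, j_uid = pr$i_uid,
                   base_i = pr$base_j, base_j = pr$base_i,
                   pair_type = pr$pair_type, stringsAsFactors = FALSE)
  duplex$pairs <- pr
  duplex
}

#' Annotate the recognition site of a duplex
#'
#' Matches an IUPAC pattern against the reference-strand sequence; if the
#' pattern does not match there, the complementary strand is searched and
#' the reference strand re-chosen so the match reads 5'->3'.  The first
#' match is kept (all matches are reported in a message when several occur);
#' no match leaves the site unset with a warning.
#'
#' @param duplex a `duplex`.
#' @param pattern IUPAC nucleotide pattern, e.g. `"GGWCC"`.
#' @return the duplex with `site_span` and `site_pattern` set.
#' @export
annotate_site <- function(duplex, pattern) {
  hits <- iupac_find(duplex$pairs$base_i, pattern)
  if (!length(hits)) {
    rev_d <- reverse_duplex(duplex)
    hits2 <- iupac_find(rev_d$pairs$base_i, pattern)
    if (length(hits2)) {
      duplex <- rev_d
      hits <- hits2
    }
  }
  duplex$site_pattern <- toupper(pattern)
  if (!length(hits)) {
    warning("site pattern ", pattern, " not found in duplex")
    duplex$site_span <- NULL
    return(duplex)
  }
  if (length(hits) > 1L) {
    message("multiple site matches at positions ",
            paste(hits, collapse = ", "), "; using the first")
  }
  duplex$site_span <- c(hits[1L], hits[1L] + nchar(pattern) - 1L)
  duplex
}
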