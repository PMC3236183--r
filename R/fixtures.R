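#' Plan for a synthetic test genome
#'
#' @param length genome length in bases.
#' @param gc GC fraction of the random background.
#' @param repeat_blocks list of repeat families, each
#'   `list(len =, n =, divergence =)`: `n` dispersed copies of a `len`-base
#'   master sequence, each copy carrying `divergence` random substitutions
#'   per base (substitution-only divergence keeps ground truth exact).
#' @param gene_density toy genes per 10 kb (genes are annotation intervals;
#'   their sequence is the background).
#' @param seed RNG seed; identical plans give identical genomes.
#' @return list of class `genome_plan`.
#' @export
genome_plan <- function(length = 1e5, gc = 0.5, repeat_blocks = list(),
                        gene_density = 1, seed = 1L) {
  stopifnot(length >= 1000, gc > 0, gc < 1, gene_density >= 0)
  structure(list(length = as.integer(length), gc = gc,
                 repeat_blocks = repeat_blocks,
                 gene_density = gene_density, seed = as.integer(seed)),
            class = "genome_plan")
}

# Place n non-overlapping intervals of given widths into [0, total), away
# from `forbidden` intervals, by rejection sampling.
place_intervals <- function(total, widths, forbidden = NULL, margin = 0L,
                            max_tries = 2000L) {
  placed <- forbidden
  out <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(total - w, 1L) - 1L
      lo <- s - margin; hi <- s + w + margin
      clash <- !is.null(placed) && nrow(placed) &&
        any(placed$start < hi & placed$end > lo)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible packing of planted features", call. = FALSE)
    out[i] <- s
    placed <- rbind(placed, data.frame(start = s, end = s + w))
  }
  out
}

#' Generate a synthetic genome with annotation
#'
#' Builds a random background sequence at the planned GC, plants repeat
#' families as dispersed near-identical copies at the stated divergence,
#' and lays down toy gene intervals. Every planted feature gets a GFF-style
#' region row (`gene` / `repeat` classes). Deterministic under the plan's
#' seed.
#'
#' @param plan a [genome_plan()].
#' @param seq_id name of the generated sequence.
#' @return list with `ref` (named character vector), `regions`
#'   (data.frame as from [read_gff_regions()]), `repeat_positions`.
#' @export
make_toy_genome <- function(plan, seq_id = "chr1") {
  stopifnot(inherits(plan, "genome_plan"))
  with_seed(plan$seed, {
    g <- random_dna(plan$length, plan$gc)
    placed <- NULL
    regions <- list()
    for (fam in plan$repeat_blocks) {
      master <- random_dna(fam$len, plan$gc)
      starts <- place_intervals(plan$length, rep(fam$len, fam$n),
                                forbidden = placed, margin = 50L)
      for (s in starts) {
        copy <- master
        nmut <- round(fam$divergence * fam$len)
        if (nmut > 0) {
          pos <- sample.int(fam$len, nmut)
          for (p in pos) {
            cur <- substr(copy, p, p)
            substr(copy, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 cur), 1L)
          }
        }
        substr(g, s + 1L, s + fam$len) <- copy
        regions[[length(regions) + 1L]] <- data.frame(
          seqid = seq_id, start = s + 1L, end = s + fam$len, strand = "+",
          type = "repeat_region", klass = "repeat",
          stringsAsFactors = FALSE)
      }
      placed <- rbind(placed,
                      data.frame(start = starts, end = starts + fam$len))
    }
    n_genes <- round(plan$gene_density * plan$length / 1e4)
    if (n_genes > 0) {
      glen <- sample(500:2000, n_genes, replace = TRUE)
      gstart <- vapply(glen, function(w)
        sample.int(plan$length - w, 1L) - 1L, integer(1))
      for (i in seq_len(n_genes))
        regions[[length(regions) + 1L]] <- data.frame(
          seqid = seq_id, start = gstart[i] + 1L, end = gstart[i] + glen[i],
          strand = sample(c("+", "-"), 1L), type = "gene", klass = "gene",
          stringsAsFactors = FALSE)
    }
    regions <- if (length(regions)) do.call(rbind, regions)
      else data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), klass = character(0),
                      stringsAsFactors = FALSE)
    list(ref = setNames(g, seq_id), regions = regions,
         repeat_positions = placed)
  })
}

#' Plan of deliberate assembly corruptions
#'
#' All coordinates are 0-based reference positions. Edits must be pairwise
#' non-overlapping, within bounds, and must not cross scaffold cuts; the
#' builder enforces this with a hard error.
#'
#' @param substitutions integer vector of substituted positions.
#' @param indels data.frame(`pos`, `len`): positive `len` inserts `len`
#'   random bases before `pos`, negative deletes `|len|` reference bases
#'   at `pos`.
#' @param relocations data.frame(`start`, `len`, `new_pos`): the segment
#'   `[start, start+len)` is excised and re-inserted before reference
#'   position `new_pos` of the same scaffold.
#' @param inversions data.frame(`start`, `len`): segment
#'   reverse-complemented in place.
#' @param dropped data.frame(`start`, `len`): reference segment absent
#'   from the assembly (creates a gap; inside a scaffold, a captured one).
#' @param n_runs data.frame(`start`, `ref_span`, `n_len`): reference
#'   segment `[start, start+ref_span)` replaced by `n_len` N characters
#'   (a scaffold-internal captured gap across an N run).
#' @return list of class `corruption_plan`.
#' @export
corruption_plan <- function(substitutions = integer(0),
                            indels = NULL, relocations = NULL,
                            inversions = NULL, dropped = NULL,
                            n_runs = NULL) {
  df0 <- function(x, cols) {
    if (is.null(x)) {
      as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
    } else {
      stopifnot(all(cols %in% names(x)))
      x[, cols, drop = FALSE]
    }
  }
  structure(list(substitutions = as.integer(substitutions),
                 indels = df0(indels, c("pos", "len")),
                 relocations = df0(relocations,
                                   c("start", "len", "new_pos")),
                 inversions = df0(inversions, c("start", "len")),
                 dropped = df0(dropped, c("start", "len")),
                 n_runs = df0(n_runs, c("start", "ref_span", "n_len"))),
            class = "corruption_plan")
}

# All edit footprints as (start, end) intervals for overlap validation.
plan_footprints <- function(plan) {
  fp <- list()
  add <- function(s, e, what) {
    if (length(s))
      fp[[length(fp) + 1L]] <<- data.frame(start = s, end = e, what = what)
  }
  add(plan$substitutions, plan$substitutions + 1L, "substitution")
  if (nrow(plan$indels))
    add(plan$indels$pos, plan$indels$pos + pmax(1L, abs(plan$indels$len)),
        "indel")
  if (nrow(plan$relocations)) {
    add(plan$relocations$start,
        plan$relocations$start + plan$relocations$len, "relocation")
    add(plan$relocations$new_pos, plan$relocations$new_pos + 1L,
        "relocation-target")
  }
  if (nrow(plan$inversions))
    add(plan$inversions$start, plan$inversions$start + plan$inversions$len,
        "inversion")
  if (nrow(plan$dropped))
    add(plan$dropped$start, plan$dropped$start + plan$dropped$len,
        "dropped")
  if (nrow(plan$n_runs))
    add(plan$n_runs$start, plan$n_runs$start + plan$n_runs$ref_span,
        "n-run")
  if (length(fp)) do.call(rbind, fp)
  else data.frame(start = integer(0), end = integer(0),
                  what = character(0))
}

#' Build a corrupted assembly with machine-readable ground truth
#'
#' The reference (single sequence) is cut into scaffolds at
#' `scaffold_cuts`, then edited per the corruption plan. The returned
#' ground truth records the planted mismatch count, indel events and
#' bases, the expected breakpoint walk (computed from the constructed
#' segment structure with the same adjacency rule the metric engine
#' documents), the uncovered reference interval set, and which uncovered
#' intervals are scaffold-captured.
#'
#' @param ref named character vector with exactly one reference sequence.
#' @param plan a [corruption_plan()].
#' @param scaffold_cuts 0-based cut positions strictly inside the
#'   sequence.
#' @param config [fidelity_config()] used for the expected breakpoint
#'   walk.
#' @return list with `assembly` (an `assembly_set`), `truth` (list:
#'   `n_mismatch`, `n_indel_events`, `n_indel_bases`, `breakpoints`,
#'   `uncovered`, `captured`, `segments`).
#' @export
corrupt_assembly <- function(ref, plan, scaffold_cuts = integer(0),
                             config = fidelity_config()) {
  stopifnot(inherits(plan, "corruption_plan"), length(ref) == 1L)
  seq_id <- names(ref)
  L <- nchar(ref[[1]])
  cuts <- sort(unique(as.integer(scaffold_cuts)))
  stopifnot(all(cuts > 0), all(cuts < L))
  bounds <- c(0L, cuts, L)
  fp <- plan_footprints(plan)
  if (nrow(fp)) {
    if (any(fp$start < 0 | fp$end > L))
      stop("corruption plan exceeds reference bounds", call. = FALSE)
    o <- order(fp$start)
    if (any(fp$end[o][-nrow(fp)] > fp$start[o][-1]))
      stop("overlapping edits in corruption plan", call. = FALSE)
    scaf_of <- findInterval(fp$start, bounds)
    if (any(findInterval(fp$end - 1L, bounds) != scaf_of))
      stop("corruption plan edit crosses a scaffold cut", call. = FALSE)
  }
  # scaffold segment lists: each segment is (rs, re, strand, kind)
  scaffolds <- lapply(seq_len(length(bounds) - 1L), function(i)
    list(list(rs = bounds[i], re = bounds[i + 1L], strand = "+",
              kind = "seq", n_len = 0L)))
  names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  split_at <- function(segs, a, b) {
    # split the forward segment containing [a, b) out of the list;
    # returns list(pre = index of first part, segs = new list, seg = part)
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      if (s$kind == "seq" && s$strand == "+" && s$rs <= a && b <= s$re) {
        parts <- list()
        if (s$rs < a) parts <- c(parts, list(list(rs = s$rs, re = a,
                                                  strand = "+",
                                                  kind = "seq",
                                                  n_len = 0L)))
        mid <- list(rs = a, re = b, strand = "+", kind = "seq", n_len = 0L)
        post <- if (b < s$re) list(list(rs = b, re = s$re, strand = "+",
                                        kind = "seq", n_len = 0L))
                else list()
        return(list(segs = append(segs[-i],
                                  c(parts, list(mid), post), after = i - 1L),
                    mid_at = i - 1L + length(parts) + 1L))
      }
    }
    stop("edit interval [", a, ",", b, ") does not lie inside a single ",
         "unedited forward segment", call. = FALSE)
  }
  apply_to_scaffold <- function(a) findInterval(a, bounds)
  # structural edits, one scaffold at a time
  for (i in seq_len(nrow(plan$dropped))) {
    d <- plan$dropped[i, ]
    si <- apply_to_scaffold(d$start)
    sp <- split_at(scaffolds[[si]], d$start, d$start + d$len)
    scaffolds[[si]] <- sp$segs[-sp$mid_at]
  }
  for (i in seq_len(nrow(plan$n_runs))) {
    d <- plan$n_runs[i, ]
    si <- apply_to_scaffold(d$start)
    sp <- split_at(scaffolds[[si]], d$start, d$start + d$ref_span)
    sp$segs[[sp$mid_at]] <- list(rs = d$start, re = d$start + d$ref_span,
                                 strand = "+", kind = "N",
                                 n_len = as.integer(d$n_len))
    scaffolds[[si]] <- sp$segs
  }
  for (i in seq_len(nrow(plan$inversions))) {
    d <- plan$inversions[i, ]
    si <- apply_to_scaffold(d$start)
    sp <- split_at(scaffolds[[si]], d$start, d$start + d$len)
    sp$segs[[sp$mid_at]]$strand <- "-"
    scaffolds[[si]] <- sp$segs
  }
  for (i in seq_len(nrow(plan$relocations))) {
    d <- plan$relocations[i, ]
    si <- apply_to_scaffold(d$start)
    if (apply_to_scaffold(d$new_pos) != si)
      stop("relocation target must lie in the same scaffold", call. = FALSE)
    sp <- split_at(scaffolds[[si]], d$start, d$start + d$len)
    seg <- sp$segs[[sp$mid_at]]
    segs <- sp$segs[-sp$mid_at]
    sp2 <- split_at(segs, d$new_pos, d$new_pos)  # zero-width split point
    segs <- append(sp2$segs[-sp2$mid_at], list(seg),
                   after = sp2$mid_at - 1L)
    # re-add the empty split marker's neighbours properly: zero-width mid
    scaffolds[[si]] <- Filter(function(s) s$kind == "N" || s$re > s$rs,
                              segs)
  }
  # small edits assigned to containing segments
  seg_edits <- function(seg) {
    subs <- plan$substitutions[plan$substitutions >= seg$rs &
                                 plan$substitutions < seg$re]
    ind <- plan$indels[plan$indels$pos >= seg$rs &
                         plan$indels$pos < seg$re, , drop = FALSE]
    list(subs = subs, indels = ind)
  }
  bases <- c("A", "C", "G", "T")
  build_seg <- function(seg) {
    if (seg$kind == "N") return(strrep("N", seg$n_len))
    s <- substr(ref[[1]], seg$rs + 1L, seg$re)
    ed <- seg_edits(seg)
    for (p in ed$subs) {
      lp <- p - seg$rs + 1L
      cur <- substr(s, lp, lp)
      substr(s, lp, lp) <- sample(setdiff(bases, cur), 1L)
    }
    if (nrow(ed$indels)) {
      ind <- ed$indels[order(ed$indels$pos, decreasing = TRUE), ,
                       drop = FALSE]
      for (j in seq_len(nrow(ind))) {
        lp <- ind$pos[j] - seg$rs
        if (ind$len[j] > 0) {
          s <- paste0(substr(s, 1L, lp),
                      random_dna(ind$len[j]), substring(s, lp + 1L))
        } else {
          s <- paste0(substr(s, 1L, lp),
                      substring(s, lp - ind$len[j] + 1L))
        }
      }
    }
    if (seg$strand == "-") s <- revcomp(s)
    s
  }
  seqs <- vapply(scaffolds, function(segs)
    paste0(vapply(segs, build_seg, character(1)), collapse = ""),
    character(1))
  assembly <- split_scaffolds(seqs, min_n_run = 10L)
  # ---- ground truth ----
  # pseudo-blocks from constructed segments (query offsets account for
  # indel length changes and N runs)
  pseudo <- list()
  for (qid in names(scaffolds)) {
    off <- 0L
    for (seg in scaffolds[[qid]]) {
      if (seg$kind == "N") { off <- off + seg$n_len; next }
      ed <- seg_edits(seg)
      net <- if (nrow(ed$indels)) sum(ed$indels$len) else 0L
      qlen <- (seg$re - seg$rs) + net
      pseudo[[length(pseudo) + 1L]] <- data.frame(
        ref_id = seq_id, ref_start = seg$rs, ref_end = seg$re,
        qry_id = qid, qry_start = off, qry_end = off + qlen,
        strand = seg$strand, stringsAsFactors = FALSE)
      off <- off + qlen
    }
  }
  pseudo <- do.call(rbind, pseudo)
  bps <- do.call(rbind, lapply(split(pseudo, pseudo$qry_id), function(b) {
    b <- b[order(b$qry_start), , drop = FALSE]
    w <- walk_breakpoints(b, config)
    if (nrow(w)) cbind(qry_id = b$qry_id[1], w) else NULL
  }))
  if (is.null(bps))
    bps <- data.frame(qry_id = character(0), qry_pos = integer(0),
                      kind = character(0), ref_id = character(0),
                      ref_pos = integer(0), stringsAsFactors = FALSE)
  rownames(bps) <- NULL
  covered <- merge_region_rows(data.frame(seqid = seq_id,
                                          start = pseudo$ref_start + 1L,
                                          end = pseudo$ref_end))
  uncovered <- set_diff(whole_genome_set(setNames(L, seq_id)), covered)
  # captured = uncovered intervals spanned by a consistent same-scaffold
  # adjacency (the same containment rule the gap accounting documents)
  span <- block_adjacencies(pseudo)
  span <- span[span$consistent & !is.na(span$rgap) & span$rgap > 0, ,
               drop = FALSE]
  captured <- logical(nrow(uncovered))
  for (i in seq_len(nrow(uncovered)))
    captured[i] <- any(span$span_lo <= uncovered$start0[i] &
                         span$span_hi >= uncovered$end0[i])
  truth <- list(
    n_mismatch = length(plan$substitutions),
    n_indel_events = nrow(plan$indels),
    n_indel_bases = if (nrow(plan$indels)) sum(abs(plan$indels$len)) else 0L,
    breakpoints = bps,
    uncovered = uncovered,
    captured = uncovered[captured, , drop = FALSE],
    segments = pseudo)
  list(assembly = assembly, truth = truth)
}

#' Draw a random isolated-edit corruption plan
#'
#' Generates a corruption plan whose edits are mutually isolated (at least
#' `min_sep` bases apart and away from scaffold cuts), sized so that each
#' planted defect maps to one expected signal: indels of 1-10 bases stay
#' inside one alignment block; dropped and N-replaced spans (100-400
#' bases) are large enough to break blocks but smaller than half the
#' relocation threshold, so they create (captured) gaps and never
#' breakpoints; relocations move 1200-2000 base segments at least
#' 2.5 x the relocation threshold away, so they are always detected.
#'
#' Structural edit positions are rejection-sampled so that no junction has
#' chance base homology (the first base on either side of every novel
#' adjacency differs from the reference continuation): planted block
#' boundaries are then recovered base-exactly by alignment, which is what
#' makes exact ground-truth comparison possible.
#'
#' @param ref named character vector with one reference sequence.
#' @param scaffold_cuts cut positions the edits must avoid.
#' @param n_sub,n_indel,n_reloc,n_inv,n_drop,n_nrun edit counts.
#' @param min_sep minimum separation between edit footprints.
#' @return a [corruption_plan()].
#' @export
random_corruption_plan <- function(ref, scaffold_cuts = integer(0),
                                   n_sub = 3L, n_indel = 2L, n_reloc = 0L,
                                   n_inv = 0L, n_drop = 1L, n_nrun = 1L,
                                   min_sep = 200L) {
  stopifnot(is.character(ref), length(ref) == 1L)
  ref_len <- nchar(ref[[1]])
  at <- function(i) substr(ref[[1]], i + 1L, i + 1L)   # 0-based base
  cmp <- function(b) chartr("ACGT", "TGCA", b)
  bounds <- sort(c(0L, scaffold_cuts, ref_len))
  placed <- data.frame(start = c(scaffold_cuts, 0L, ref_len),
                       end = c(scaffold_cuts, 0L, ref_len) + 1L)
  draw <- function(w, ok_fun = function(s) TRUE, max_tries = 500L) {
    for (t in seq_len(max_tries)) {
      s <- place_intervals(ref_len, w, forbidden = placed,
                           margin = min_sep)
      if (ok_fun(s)) {
        placed <<- rbind(placed, data.frame(start = s, end = s + w))
        return(s)
      }
    }
    stop("could not place a homology-free junction", call. = FALSE)
  }
  # no-homology predicates for a novel adjacency ref[u-1] | ref[v]
  junction_ok <- function(u, v) at(u) != at(v) && at(u - 1L) != at(v - 1L)
  relocations <- NULL
  if (n_reloc) {
    rows <- lapply(seq_len(n_reloc), function(i) {
      w <- sample(1200:2000, 1L)
      for (t in seq_len(2000L)) {
        s <- sample.int(ref_len - w, 1L) - 1L
        scaf <- findInterval(s, bounds)
        lo <- bounds[scaf]; hi <- bounds[scaf + 1L]
        if (s - min_sep <= lo || s + w + min_sep >= hi) next
        if (any(placed$start < s + w + min_sep &
                  placed$end > s - min_sep)) next
        if (!junction_ok(s, s + w)) next
        c0 <- sample((lo + min_sep):(hi - min_sep), 1L)
        if (c0 >= s - min_sep && c0 <= s + w + min_sep) next
        if (abs(c0 - s) <= 2500) next
        if (any(placed$start < c0 + min_sep & placed$end > c0 - min_sep))
          next
        # insertion junctions: ...ref[c-1] | seg | ref[c]...
        if (at(s) == at(c0) || at(c0 - 1L) == at(s - 1L)) next
        if (at(c0) == at(s + w) || at(c0 - 1L) == at(s + w - 1L)) next
        placed <<- rbind(placed,
                         data.frame(start = c(s, c0),
                                    end = c(s + w, c0 + 1L)))
        return(data.frame(start = s, len = w, new_pos = c0))
      }
      stop("could not place a homology-free relocation", call. = FALSE)
    })
    relocations <- do.call(rbind, rows)
  }
  subs <- if (n_sub) vapply(rep(1L, n_sub), draw, integer(1)) else integer(0)
  indels <- NULL
  if (n_indel) {
    pos <- vapply(rep(12L, n_indel), draw, integer(1))
    indels <- data.frame(pos = pos,
                         len = sample(c(-10:-1, 1:10), n_indel,
                                      replace = TRUE))
  }
  dropped <- NULL
  if (n_drop) {
    dropped <- do.call(rbind, lapply(seq_len(n_drop), function(i) {
      w <- sample(100:400, 1L)
      s <- draw(w, function(s) junction_ok(s, s + w))
      data.frame(start = s, len = w)
    }))
  }
  n_runs <- NULL
  if (n_nrun) {
    n_runs <- do.call(rbind, lapply(seq_len(n_nrun), function(i) {
      w <- sample(100:400, 1L)
      s <- draw(w)      # N flanks block extension on their own
      data.frame(start = s, ref_span = w,
                 n_len = max(50L, w + sample(-30:30, 1L)))
    }))
  }
  inversions <- NULL
  if (n_inv) {
    inversions <- do.call(rbind, lapply(seq_len(n_inv), function(i) {
      w <- sample(300:1500, 1L)
      s <- draw(w, function(s)
        cmp(at(s + w - 1L)) != at(s) && cmp(at(s - 1L)) != at(s + w))
      data.frame(start = s, len = w)
    }))
  }
  corruption_plan(substitutions = subs, indels = indels,
                  relocations = relocations, inversions = inversions,
                  dropped = dropped, n_runs = n_runs)
}
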