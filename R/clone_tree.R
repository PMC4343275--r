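#' Build a clonal lineage with genome-doubling events
#'
#' Constructs a clone tree in one of three modes describing how the two
#' sub-tetraploid subpopulations (AA, AB) arose from a hypodiploid ancestral
#' population (H):
#'
#' * `"dual_endoreduplication"` - the hypodiploid population splits into two
#'   genetically distinct clones (branches `II` and `III`); each doubles its
#'   genome independently (clones `IV` and `V`), together forming the AA
#'   mixture; AB (clone `VI`) derives from the clone-`V` lineage only.
#' * `"cell_fusion"` - a lineage diverges from H for a long time (branch `Q`,
#'   the AA-AB markers), then forms AA by fusing with a cell related to H
#'   (branch `P`) and forms AB by endoreduplication.
#' * `"linear"` - a single doubling in one H-derived cell gives rise to both
#'   AA and AB; under this model no mutation can be shared by AA and H but
#'   absent from AB (the single-cell bottleneck).
#'
#' Mutations (SNV/indel/SV identifiers) are assigned to branches according to
#' `branch_weights`; a clone's mutation set is the union of mutations on its
#' root path. When a `reference_model` is supplied, hypodiploid chromosome
#' losses, copy-number events and LOH events are placed on the genome
#' (non-overlapping); otherwise the tree carries set structure only.
#'
#' @param mode lineage mode, see above.
#' @param n_snv,n_indel,n_sv total numbers of somatic mutations to plant.
#' @param branch_weights named numeric vector of branch mutation weights
#'   (names are branch/node names; must sum to 1). `NULL` uses mode-specific
#'   defaults echoing published sharing proportions.
#' @param ref optional `reference_model`; required to place copy-number, loss
#'   and LOH regions.
#' @param loss_fraction fraction of the genome at copy 1 in the hypodiploid
#'   founder (default 0.30, giving mean ploidy 1.7 N).
#' @param f_aa fraction of the AA subpopulation composed of the AB-related
#'   clone (clone V) in dual mode.
#' @param cna_spec,loh_spec `"default"` for mode defaults (needs `ref`),
#'   `NULL` for none, or a data.frame (`node`, `chrom`, `start`, `end`,
#'   `delta` for CNA; `node`, `chrom`, `start`, `end` for LOH; 0-based
#'   half-open).
#' @param fusion_parents (cell_fusion mode) names of the two parental nodes
#'   fused into AA. Fusing clones of unequal doubling history is rejected.
#' @param seed integer master seed.
#' @return An object of class `clone_tree`.
#' @export
build_lineage <- function(mode = c("dual_endoreduplication", "cell_fusion", "linear"),
                          n_snv = 2000, n_indel = 400, n_sv = 60,
                          branch_weights = NULL,
                          ref = NULL,
                          loss_fraction = 0.30,
                          f_aa = 0.40,
                          cna_spec = "default",
                          loh_spec = "default",
                          fusion_parents = c("Q", "P"),
                          seed = 1) {
  mode <- match.arg(mode)
  if (any(c(n_snv, n_indel, n_sv) < 0)) stop("mutation counts must be >= 0")
  stopifnot_scalar_prob(loss_fraction, "loss_fraction")
  stopifnot_scalar_prob(f_aa, "f_aa")

  topo <- lineage_topology(mode, f_aa, fusion_parents)
  weights <- branch_weights %||% topo$default_weights
  if (is.null(names(weights)) || !all(names(weights) %in% topo$nodes$name)) {
    stop("branch_weights must be named by tree nodes")
  }
  if (any(weights < 0)) stop("branch weights must be >= 0")

  tree <- structure(list(
    mode = mode,
    nodes = topo$nodes,
    doublings = topo$doublings,
    fusions = topo$fusions,
    clone_mixtures = topo$clone_mixtures,
    f_aa = f_aa,
    loss_fraction = loss_fraction,
    events = empty_events(),
    mutations = data.frame(id = character(0), class = character(0),
                           node = character(0), stringsAsFactors = FALSE),
    seed = seed
  ), class = "clone_tree")

  # mutations per branch: largest-remainder allocation of each class
  tree$mutations <- with_stream(seed, "lineage/mutations", {
    alloc <- function(total, class) {
      if (total == 0 || sum(weights) == 0) {
        return(NULL)
      }
      counts <- largest_remainder(total, weights / sum(weights))
      node <- rep(names(weights), counts)
      data.frame(id = sprintf("%s_%05d", tolower(class), seq_along(node)),
                 class = class, node = node, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, Filter(Negate(is.null),
                                 list(alloc(n_snv, "SNV"),
                                      alloc(n_indel, "indel"),
                                      alloc(n_sv, "SV"))))
    out %||% tree$mutations
  })

  # genomic events need a reference to place regions on
  if (!is.null(ref)) {
    tree$events <- with_stream(seed, "lineage/events", {
      place_lineage_events(tree, ref, loss_fraction, cna_spec, loh_spec, topo)
    })
  } else if (is.data.frame(cna_spec) || is.data.frame(loh_spec)) {
    ev <- empty_events()
    if (is.data.frame(cna_spec)) {
      ev <- rbind(ev, data.frame(node = cna_spec$node, type = "cna",
                                 chrom = cna_spec$chrom, start = cna_spec$start,
                                 end = cna_spec$end, delta = cna_spec$delta,
                                 tag = "cna", stringsAsFactors = FALSE))
    }
    if (is.data.frame(loh_spec)) {
      ev <- rbind(ev, data.frame(node = loh_spec$node, type = "loh",
                                 chrom = loh_spec$chrom, start = loh_spec$start,
                                 end = loh_spec$end, delta = 0,
                                 tag = "loh", stringsAsFactors = FALSE))
    }
    tree$events <- ev
  }

  validate_clone_tree(tree)
  tree
}

empty_events <- function() {
  data.frame(node = character(0), type = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), delta = numeric(0),
             tag = character(0), stringsAsFactors = FALSE)
}

largest_remainder <- function(total, p) {
  raw <- total * p
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

lineage_topology <- function(mode, f_aa, fusion_parents) {
  if (mode == "dual_endoreduplication") {
    # IIIv is the pre-doubling private branch of the cell that doubles into
    # clone V: its mutations are the AA-AB marker class (2 of 4 copies after
    # doubling); V is the post-doubling lineage shared by AA_V and VI.
    nodes <- data.frame(
      name = c("normal", "n1", "II", "III", "H_II", "IV", "H_III", "IIIv",
               "V", "AA_V", "VI"),
      parent = c(NA, "normal", "n1", "n1", "II", "II", "III", "III", "IIIv",
                 "V", "V"),
      stringsAsFactors = FALSE)
    list(nodes = nodes,
         doublings = c("IV", "V"),
         fusions = list(),
         clone_mixtures = list(
           D = c(normal = 1),
           H = c(H_II = 0.5, H_III = 0.5),
           AA = c(IV = 1 - f_aa, AA_V = f_aa),
           AB = c(VI = 1)),
         # AA-AB markers (IIIv) outnumber AA-H markers (II): the long
         # pre-doubling divergence of the V lineage is what makes the
         # AA/AB sister grouping dominate the H+AA signal in distance space
         default_weights = c(n1 = 0.14, III = 0.08, II = 0.08, IIIv = 0.20,
                             H_II = 0.06, H_III = 0.06, IV = 0.06,
                             AA_V = 0.06, VI = 0.26))
  } else if (mode == "cell_fusion") {
    nodes <- data.frame(
      name = c("normal", "n1", "Hc", "H_leaf", "P", "Q", "AAf", "VIb"),
      parent = c(NA, "normal", "n1", "Hc", "Hc", "n1", fusion_parents[1], "Q"),
      stringsAsFactors = FALSE)
    fus <- list(AAf = fusion_parents)
    topo <- list(nodes = nodes,
                 doublings = "VIb",
                 fusions = fus,
                 clone_mixtures = list(
                   D = c(normal = 1),
                   H = c(H_leaf = 1),
                   AA = c(AAf = 1),
                   AB = c(VIb = 1)),
                 default_weights = c(n1 = 0.20, Hc = 0.15, H_leaf = 0.10,
                                     P = 0.05, Q = 0.20, AAf = 0.10, VIb = 0.20))
    check_fusion_compat(topo)
    topo
  } else {
    nodes <- data.frame(
      name = c("normal", "n1", "Hl", "T", "W", "AAl", "ABl"),
      parent = c(NA, "normal", "n1", "n1", "T", "W", "W"),
      stringsAsFactors = FALSE)
    list(nodes = nodes,
         doublings = "W",
         fusions = list(),
         clone_mixtures = list(
           D = c(normal = 1),
           H = c(Hl = 1),
           AA = c(AAl = 1),
           AB = c(ABl = 1)),
         default_weights = c(n1 = 0.25, Hl = 0.15, T = 0.20, W = 0.15,
                             AAl = 0.10, ABl = 0.15))
  }
}

# Fusion of two cells is only meaningful between clones with the same doubling
# history (both undoubled here): summing a tetraploid and a diploid genome is
# rejected as an incompatible-ploidy fusion.
check_fusion_compat <- function(topo) {
  n_doublings <- function(node) {
    k <- 0L
    while (!is.na(node)) {
      if (node %in% topo$doublings) k <- k + 1L
      node <- topo$nodes$parent[match(node, topo$nodes$name)]
    }
    k
  }
  for (fnode in names(topo$fusions)) {
    p <- topo$fusions[[fnode]]
    if (!all(p %in% topo$nodes$name)) {
      stop("fusion parents must be tree nodes")
    }
    if (n_doublings(p[1]) != n_doublings(p[2])) {
      stop("fusion of clones with incompatible ploidies (unequal doubling history)")
    }
  }
  invisible(TRUE)
}

# Place hypodiploid loss regions, CNA events and LOH events on the genome,
# mutually non-overlapping so planted states stay interpretable.
place_lineage_events <- function(tree, ref, loss_fraction, cna_spec, loh_spec, topo) {
  used <- list()
  # pad keeps planted events separated so distinct events stay resolvable
  # as distinct segments at the default read-depth bin width
  pad <- 5e5
  place_region <- function(size) {
    for (try in 1:500) {
      i <- sample.int(nrow(ref$chromosomes), 1,
                      prob = ref$chromosomes$length)
      L <- ref$chromosomes$length[i]
      if (L <= size) next
      start <- floor(stats::runif(1, 0, L - size))
      cand <- data.frame(chrom = ref$chromosomes$name[i], start = start,
                         end = start + size, stringsAsFactors = FALSE)
      clash <- FALSE
      for (u in used) {
        if (u$chrom == cand$chrom && u$start < cand$end + pad &&
            cand$start < u$end + pad) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        used[[length(used) + 1]] <<- cand
        return(cand)
      }
    }
    stop("could not place a non-overlapping event region; genome too crowded")
  }

  trunk <- trunk_node(tree)
  if (identical(cna_spec, "default")) {
    cna_spec <- default_cna_spec(tree$mode)
  }
  if (identical(loh_spec, "default")) {
    loh_spec <- default_loh_spec(tree$mode)
  }

  # requested events, before genomic placement
  req <- empty_events()[, c("node", "type", "delta", "tag")]
  req$size <- numeric(0)
  if (loss_fraction > 0) {
    # hypodiploid chromosome losses on the trunk: copy 2 -> 1 over loss_fraction
    n_loss <- 7L
    req <- rbind(req, data.frame(node = rep(trunk, n_loss), type = "cna",
                                 delta = -1, tag = "hypodiploid_loss",
                                 size = loss_fraction * ref$genome_length / n_loss,
                                 stringsAsFactors = FALSE))
  }
  place_df <- function(spec, type, tag) {
    if (!is.data.frame(spec) || nrow(spec) == 0) {
      return(NULL)
    }
    data.frame(node = spec$node, type = type,
               delta = if (type == "cna") spec$delta else 0, tag = tag,
               size = if (all(c("chrom", "start", "end") %in% names(spec)))
                 spec$end - spec$start else spec$size,
               chrom = if ("chrom" %in% names(spec)) spec$chrom else NA_character_,
               start = if ("start" %in% names(spec)) spec$start else NA_real_,
               end = if ("end" %in% names(spec)) spec$end else NA_real_,
               stringsAsFactors = FALSE)
  }
  req$chrom <- NA_character_
  req$start <- NA_real_
  req$end <- NA_real_
  req <- rbind(req, place_df(cna_spec, "cna", "cna"),
               place_df(loh_spec, "loh", "loh"))
  if (nrow(req) == 0) {
    return(empty_events())
  }
  # register explicit regions, then place the rest largest-first so big
  # regions are not squeezed out of a crowded genome
  explicit <- !is.na(req$start)
  for (i in which(explicit)) {
    used[[length(used) + 1]] <- req[i, c("chrom", "start", "end")]
  }
  for (i in order(ifelse(explicit, -Inf, req$size), decreasing = TRUE)) {
    if (explicit[i]) next
    r <- place_region(round(req$size[i]))
    req$chrom[i] <- r$chrom
    req$start[i] <- r$start
    req$end[i] <- r$end
  }
  ev <- data.frame(node = req$node, type = req$type, chrom = req$chrom,
                   start = req$start, end = req$end, delta = req$delta,
                   tag = req$tag, stringsAsFactors = FALSE)

  bad <- !(ev$node %in% tree$nodes$name)
  if (any(bad)) {
    stop("event spec refers to unknown nodes: ", paste(unique(ev$node[bad]), collapse = ", "))
  }
  rownames(ev) <- NULL
  ev
}

trunk_node <- function(tree) {
  root <- tree$nodes$name[is.na(tree$nodes$parent)]
  kids <- tree$nodes$name[!is.na(tree$nodes$parent) & tree$nodes$parent == root]
  kids[1]
}

# Default copy-number event plan. Deltas are sized so that every planted event
# crosses the published gain/loss ratio thresholds (>=1.4 / <=0.8) in every
# sample carrying it, including mixed-clone samples (AA is a 70/30 clone
# mixture at the default f_aa = 0.4).
default_cna_spec <- function(mode) {
  if (mode == "dual_endoreduplication") {
    data.frame(
      node = c("n1", "II", "II", "III", "III", "IIIv", "IIIv", "IV", "AA_V",
               "H_II", "H_III", "VI", "VI"),
      delta = c(2, -2, 2, 4, -2, 4, -2, 4, 8, -2, 2, 2, -2),
      size = c(1.4e6, 1.1e6, 1.0e6, 1.0e6, 1.0e6, 1.0e6, 1.0e6, 1.0e6, 1.0e6,
               0.9e6, 0.9e6, 1.0e6, 1.0e6),
      stringsAsFactors = FALSE)
  } else if (mode == "cell_fusion") {
    data.frame(
      node = c("n1", "Hc", "Q", "AAf", "VIb"),
      delta = c(2, -1, 2, 4, -2),
      size = c(1.4e6, 1.1e6, 1.0e6, 1.0e6, 1.0e6),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      node = c("n1", "Hl", "T", "AAl", "ABl"),
      delta = c(2, -1, 2, 4, -2),
      size = c(1.4e6, 1.1e6, 1.0e6, 1.0e6, 1.0e6),
      stringsAsFactors = FALSE)
  }
}

default_loh_spec <- function(mode) {
  node <- switch(mode,
                 dual_endoreduplication = "VI",
                 cell_fusion = "VIb",
                 linear = "ABl")
  data.frame(node = c(node, node), size = c(2.5e6, 2.5e6), stringsAsFactors = FALSE)
}

validate_clone_tree <- function(tree) {
  roots <- tree$nodes$name[is.na(tree$nodes$parent)]
  if (length(roots) != 1) stop("clone tree must have a single root")
  if (!all(tree$nodes$parent[!is.na(tree$nodes$parent)] %in% tree$nodes$name)) {
    stop("parent links must reference tree nodes")
  }
  if (anyDuplicated(tree$mutations$id)) stop("mutation ids must be unique")
  if (nrow(tree$mutations) > 0 && !all(tree$mutations$node %in% tree$nodes$name)) {
    stop("mutations must be assigned to tree nodes")
  }
  mixes <- tree$clone_mixtures
  for (s in names(mixes)) {
    if (abs(sum(mixes[[s]]) - 1) > 1e-8) {
      stop(sprintf("clone mixture of sample %s must sum to 1", s))
    }
    if (!all(names(mixes[[s]]) %in% tree$nodes$name)) {
      stop("clone mixtures must reference tree nodes")
    }
  }
  invisible(tree)
}

# Ancestor set (including self) of a node; fusion nodes inherit both parents.
ancestor_sets <- function(tree) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(node) {
    if (!is.null(memo[[node]])) {
      return(memo[[node]])
    }
    parent <- tree$nodes$parent[match(node, tree$nodes$name)]
    anc <- if (node %in% names(tree$fusions)) {
      p <- tree$fusions[[node]]
      union(node, union(get_anc(p[1]), get_anc(p[2])))
    } else if (is.na(parent)) {
      node
    } else {
      union(node, get_anc(parent))
    }
    memo[[node]] <- anc
    anc
  }
  stats::setNames(lapply(tree$nodes$name, get_anc), tree$nodes$name)
}

#' Sharing pattern of each branch across the tumor samples
#'
#' A branch's mutations are present in every sample whose clone mixture
#' includes a descendant (or the branch's own clone).
#'
#' @param tree a `clone_tree`.
#' @param tumor_labels samples to report patterns over.
#' @return Named character vector: node -> pattern (e.g. `"H+AA"`), `""` for
#'   branches private to the normal lineage.
#' @export
branch_patterns <- function(tree, tumor_labels = c("H", "AA", "AB")) {
  anc <- ancestor_sets(tree)
  vapply(tree$nodes$name, function(node) {
    carriers <- vapply(tumor_labels, function(s) {
      mix <- tree$clone_mixtures[[s]]
      any(vapply(names(mix)[mix > 0], function(cl) node %in% anc[[cl]], logical(1)))
    }, logical(1))
    paste(tumor_labels[carriers], collapse = "+")
  }, character(1))
}

#' Per-clone allele copy state at a set of sites
#'
#' Walks the clone's root path applying, in order on each branch: genome
#' doubling (or fusion: copy counts of the two parents are summed), then
#' copy-number and LOH events, then new mutation acquisitions (one mutant copy
#' each). Copy losses and LOH remove the mutant homolog first; gains amplify
#' the reference homolog. Germline sites start heterozygous (1 of 2) at the
#' root.
#'
#' @param tree a `clone_tree`.
#' @param clone clone (node) name.
#' @param sites data.frame with `chrom`, `pos` (1-based) and `origin` (a node
#'   name, `"germline"`, or `"none"` for copy number only).
#' @return List with integer vectors `m` (mutant copies) and `t` (total
#'   copies) aligned to `sites`.
#' @export
copy_state <- function(tree, clone, sites) {
  if (!clone %in% tree$nodes$name) stop("unknown clone: ", clone)
  n <- nrow(sites)
  memo <- new.env(parent = emptyenv())
  root <- tree$nodes$name[is.na(tree$nodes$parent)]

  in_region <- function(ev_row) {
    sites$chrom == ev_row$chrom & sites$pos > ev_row$start & sites$pos <= ev_row$end
  }

  state <- function(node) {
    if (!is.null(memo[[node]])) {
      return(memo[[node]])
    }
    if (node == root) {
      s <- list(m = as.integer(sites$origin == "germline"), t = rep(2L, n))
    } else if (node %in% names(tree$fusions)) {
      p <- tree$fusions[[node]]
      s1 <- state(p[1])
      s2 <- state(p[2])
      s <- list(m = s1$m + s2$m, t = s1$t + s2$t)
    } else {
      parent <- tree$nodes$parent[match(node, tree$nodes$name)]
      s <- state(parent)
    }
    if (node != root || node %in% tree$doublings) {
      if (node %in% tree$doublings) {
        s$m <- s$m * 2L
        s$t <- s$t * 2L
      }
      evs <- tree$events[tree$events$node == node, , drop = FALSE]
      if (nrow(evs) > 0) {
        for (i in seq_len(nrow(evs))) {
          hit <- in_region(evs[i, ])
          if (!any(hit)) next
          if (evs$type[i] == "cna") {
            d <- evs$delta[i]
            if (d < 0) {
              k <- as.integer(-d)
              s$m[hit] <- pmax(0L, s$m[hit] - k)
              s$t[hit] <- pmax(0L, s$t[hit] - k)
            } else {
              s$t[hit] <- s$t[hit] + as.integer(d)
            }
          } else if (evs$type[i] == "loh") {
            s$m[hit] <- 0L
          }
        }
      }
      acq <- sites$origin == node & s$t > 0L
      s$m[acq] <- pmin(s$t[acq], s$m[acq] + 1L)
    }
    memo[[node]] <- s
    s
  }
  state(clone)
}

# Total copy number of a clone at arbitrary (chrom, pos) sites.
clone_total_copies <- function(tree, clone, chrom, pos) {
  sites <- data.frame(chrom = chrom, pos = pos, origin = "none",
                      stringsAsFactors = FALSE)
  copy_state(tree, clone, sites)$t
}

# Genome-wide mean copy number of a clone (length-weighted over a grid).
clone_mean_copies <- function(tree, clone, ref, grid_n = 2000) {
  per_chrom <- round(grid_n * ref$chromosomes$length / ref$genome_length)
  pts <- do.call(rbind, lapply(seq_len(nrow(ref$chromosomes)), function(i) {
    k <- max(1, per_chrom[i])
    data.frame(chrom = ref$chromosomes$name[i],
               pos = round(seq(1, ref$chromosomes$length[i], length.out = k)),
               stringsAsFactors = FALSE)
  }))
  mean(clone_total_copies(tree, clone, pts$chrom, pts$pos))
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree (%s): %d nodes, %d mutations, %d genomic events\n",
              x$mode, nrow(x$nodes), nrow(x$mutations), nrow(x$events)))
  pat <- branch_patterns(x)
  tab <- table(factor(pat[x$mutations$node], levels = unique(pat)))
  tab <- tab[tab > 0]
  if (length(tab)) {
    cat("  mutations by sharing pattern:\n")
    for (p in names(tab)) cat(sprintf("    %-10s %d\n", ifelse(p == "", "(none)", p), tab[[p]]))
  }
  invisible(x)
}
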