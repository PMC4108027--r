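#' Reference species tree for simulation
#'
#' A rooted, ultrametric ten-species tree: the chlorophyte *Chlamydomonas*
#' as outgroup, then the moss *Physcomitrella*, the lycophyte *Selaginella*,
#' two monocots (rice, sorghum) and five eudicots. Branch lengths are in
#' arbitrary time units with a root depth of 1; internal nodes carry clade
#' labels, with `land_plants` marking the bryophyte/tracheophyte split at
#' which ground-truth copy numbers are usually read.
#'
#' @return a `phylo` with named internal nodes.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(chlamydomonas:1,(physcomitrella:0.85,(selaginella:0.75,",
    "((oryza:0.35,sorghum:0.35)monocots:0.25,",
    "(vitis:0.45,(carica:0.35,(populus:0.3,",
    "(arabidopsis:0.25,medicago:0.25)malvid_fabid:0.05)rosids:0.05)",
    "core_eudicots:0.1)eudicots:0.15)angiosperms:0.15)",
    "tracheophytes:0.1)land_plants:0.15)root;"
  )
  ape::read.tree(text = txt)
}

#' Simulation settings for the duplication--loss gene-family model
#'
#' Gene families evolve down the species tree by a linear birth--death
#' process: each gene copy on a branch duplicates at rate `dup_rate` and is
#' lost at rate `loss_rate` (events per copy per unit branch length);
#' every copy present at a speciation node is inherited by both descendant
#' branches. The family starts with `k0` copies at the species-tree root.
#'
#' @param species_tree a rooted `phylo` with branch lengths and labelled
#'   internal nodes; default [default_species_tree()].
#' @param k0 positive integer, copies at the root.
#' @param dup_rate,loss_rate non-negative rates.
#' @param p_weak fraction of internal gene-tree edges given a support below
#'   the collapse threshold by [degrade_supports()] (0 = all supports 100).
#' @param threshold collapse threshold the support model targets.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(species_tree = default_species_tree(),
                              k0 = 1, dup_rate = 0.3, loss_rate = 0.2,
                              p_weak = 0, threshold = 50, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length),
            k0 >= 1, dup_rate >= 0, loss_rate >= 0,
            p_weak >= 0, p_weak <= 1)
  structure(
    list(species_tree = species_tree, k0 = as.integer(k0),
         dup_rate = dup_rate, loss_rate = loss_rate,
         p_weak = p_weak, threshold = threshold, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate one gene family along the species tree
#'
#' Runs the duplication--loss model of a [simulation_config()] and returns
#' the pruned gene tree (copies extinct everywhere are removed, and
#' single-child nodes suppressed with their branch lengths merged) together
#' with the ground truth: for every species-tree node, the number of gene
#' copies entering its subtree, both raw (`copies_raw`) and restricted to
#' copies with at least one surviving descendant (`copies` -- the quantity a
#' topology-based method can hope to recover). All internal supports are
#' initially 100; see [degrade_supports()].
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed`.
#' @return an object of class `simulated_family`: list with `tree` (a
#'   taxon-annotated `gene_tree`, or `NULL` if the family went extinct),
#'   `truth` (tibble: `node_label`, `copies`, `copies_raw`), `events`
#'   (tibble: `type`, `branch`, `time`), `extinct`, `config`.
#' @examples
#' fam <- simulate_family(simulation_config(k0 = 2, seed = 42))
#' truth_at_split(fam)
#' @export
simulate_family <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- config$species_tree
  n <- length(st$tip.label)
  nd <- tree_nodes(st)
  labels <- nd$label
  lam <- config$dup_rate
  mu <- config$loss_rate

  env <- new.env(parent = emptyenv())
  env$raw <- stats::setNames(integer(length(labels)), labels)
  env$alive <- stats::setNames(integer(length(labels)), labels)
  env$events <- list()
  env$leaf_i <- stats::setNames(integer(n), st$tip.label)

  log_event <- function(type, branch, time) {
    env$events[[length(env$events) + 1L]] <-
      list(type = type, branch = branch, time = time)
  }

  # one gene copy arriving exactly at species node v;
  # returns list(str, extra) or NULL if it leaves no sampled descendant
  sim_at_node <- function(v) {
    env$raw[labels[v]] <- env$raw[labels[v]] + 1L
    res <- if (v <= n) {
      env$leaf_i[v] <- env$leaf_i[v] + 1L
      list(str = paste0(st$tip.label[v], "_", env$leaf_i[v]), extra = 0)
    } else {
      parts <- list()
      for (c in nd$children[[v]]) {
        r <- sim_edge(c, nd$elen[c], 0)
        if (!is.null(r)) parts[[length(parts) + 1L]] <- r
      }
      if (length(parts) == 0) NULL
      else if (length(parts) == 1) {
        list(str = parts[[1]]$str, extra = parts[[1]]$len)
      } else {
        inner <- vapply(parts, function(p)
          paste0(p$str, ":", format(p$len, digits = 12)), character(1))
        list(str = paste0("(", paste(inner, collapse = ","), ")"), extra = 0)
      }
    }
    if (!is.null(res)) env$alive[labels[v]] <- env$alive[labels[v]] + 1L
    res
  }

  # one gene lineage part-way down the edge into species node v;
  # returns list(str, len = length of its top gene-tree edge) or NULL
  sim_edge <- function(v, t_total, t_done) {
    remaining <- t_total - t_done
    rate <- lam + mu
    w <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (w >= remaining) {
      r <- sim_at_node(v)
      if (is.null(r)) return(NULL)
      return(list(str = r$str, len = remaining + r$extra))
    }
    if (stats::runif(1) < mu / rate) {
      log_event("loss", labels[v], t_done + w)
      return(NULL)
    }
    log_event("duplication", labels[v], t_done + w)
    r1 <- sim_edge(v, t_total, t_done + w)
    r2 <- sim_edge(v, t_total, t_done + w)
    alive <- Filter(Negate(is.null), list(r1, r2))
    if (length(alive) == 0) return(NULL)
    if (length(alive) == 1) {
      return(list(str = alive[[1]]$str, len = w + alive[[1]]$len))
    }
    list(str = paste0("(",
                      alive[[1]]$str, ":", format(alive[[1]]$len, digits = 12), ",",
                      alive[[2]]$str, ":", format(alive[[2]]$len, digits = 12),
                      ")"),
         len = w)
  }

  roots <- Filter(Negate(is.null), lapply(seq_len(config$k0),
                                          function(i) sim_at_node(nd$root)))
  tree <- NULL
  extinct <- length(roots) == 0
  if (!extinct) {
    txt <- if (length(roots) == 1) {
      paste0(roots[[1]]$str, ";")
    } else {
      paste0("(", paste(vapply(roots, function(r)
        paste0(r$str, ":", format(r$extra, digits = 12)), character(1)),
        collapse = ","), ");")
    }
    if (!grepl("(", txt, fixed = TRUE)) { # single surviving leaf
      tree <- read_gene_tree(txt)
    } else {
      tree <- as_gene_tree(ape::read.tree(text = txt))
      tree$node.label <- rep("100", tree$Nnode)
      tree$node.label[1] <- "" # the root carries no support
    }
    sp <- sub("_[0-9]+$", "", tree$tip.label)
    names(sp) <- tree$tip.label
    attr(tree, "species") <- sp
  }

  events <- if (length(env$events) == 0) {
    tibble::tibble(type = character(0), branch = character(0),
                   time = numeric(0))
  } else {
    dplyr::bind_rows(lapply(env$events, tibble::as_tibble))
  }
  truth <- tibble::tibble(
    node_label = labels,
    copies = unname(env$alive[labels]),
    copies_raw = unname(env$raw[labels])
  )
  structure(
    list(tree = tree, truth = truth, events = events,
         extinct = extinct, config = config),
    class = "simulated_family"
  )
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("<simulated_family>",
      if (x$extinct) "EXTINCT (no surviving copies)\n"
      else sprintf("%d surviving genes; truth at bryophyte/tracheophyte split = %d\n",
                   length(x$tree$tip.label), truth_at_split(x)))
  invisible(x)
}

#' Ground-truth copy number at a species-tree node
#'
#' @param family a `simulated_family`.
#' @param node_label species-tree node label; default `"land_plants"`, the
#'   bryophyte/tracheophyte split.
#' @param raw count all entering copies (`TRUE`) or only those with
#'   surviving descendants (default)?
#' @return integer.
#' @export
truth_at_split <- function(family, node_label = "land_plants", raw = FALSE) {
  stopifnot(inherits(family, "simulated_family"))
  i <- match(node_label, family$truth$node_label)
  if (is.na(i)) stop("no species-tree node labelled '", node_label, "'",
                     call. = FALSE)
  if (raw) family$truth$copies_raw[i] else family$truth$copies[i]
}

#' @rdname truth_at_split
#' @param x a `simulated_family`.
#' @param ... unused.
#' @export
tidy.simulated_family <- function(x, ...) x$truth

#' Degrade bootstrap supports to emulate poorly resolved trees
#'
#' Assigns exactly `round(p * n)` of the `n` internal non-root nodes a
#' support drawn uniformly in `[0, threshold)` (so they collapse at
#' `threshold`) and support 100 to the rest. This emulates the large
#' polytomies of real bootstrap trees without simulating sequences.
#'
#' @param x a `simulated_family` or a `gene_tree`.
#' @param p fraction in \[0, 1\] of internal edges made weak.
#' @param threshold collapse threshold the weak supports fall below.
#' @param seed optional seed for reproducible degradation.
#' @return object of the same type with supports reassigned.
#' @export
degrade_supports <- function(x, p, threshold = 50, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (inherits(x, "simulated_family")) {
    if (!x$extinct) {
      x$tree <- degrade_supports(x$tree, p, threshold, seed)
    }
    return(x)
  }
  stopifnot(inherits(x, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  tree <- x
  if (tree$Nnode <= 1) return(as_gene_tree(tree))
  nd <- tree_nodes(tree)
  n <- nd$n_tip
  internal <- n + seq_len(tree$Nnode)
  non_root <- internal[internal != nd$root]
  m <- length(non_root)
  k <- round(p * m)
  weak <- if (k > 0) non_root[sample.int(m, k)] else integer(0)
  lab <- rep("100", tree$Nnode)
  lab[nd$root - n] <- ""
  if (k > 0) {
    lab[weak - n] <- format(stats::runif(k, 0, threshold), digits = 6)
  }
  tree$node.label <- lab
  as_gene_tree(tree)
}
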