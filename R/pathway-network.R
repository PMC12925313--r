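#' Load a reference nucleotide-sugar reaction network
#'
#' The network is a directed graph of reactions between metabolites, running
#' from central-carbon entry points (e.g. fructose-6-phosphate,
#' ribulose-5-phosphate, sedoheptulose-7-phosphate) to activated-sugar
#' products. Each reaction is gated by gene families: a list of alternatives
#' (isoenzymes, OR), each alternative a set of families that must all be
#' present (complex, AND).
#'
#' The YAML config has blocks:
#' \preformatted{
#' metabolites: [F6P, G6P, ...]
#' sources: [F6P, ...]
#' reactions:
#'   - id: pgi
#'     substrate: F6P
#'     product: G6P
#'     genes: [[K01810]]
#' products:
#'   UDP-glucose: galU        # sugar -> terminal reaction id
#' }
#'
#' @param config Path to the YAML file, or an equivalent list.
#' @return A validated \code{reference_network} object (list with elements
#'   \code{metabolites}, \code{sources}, \code{reactions}, \code{products}).
#' @export
load_network <- function(config) {
  x <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- c("metabolites", "sources", "reactions", "products")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("network config missing block(s): ",
                         paste(miss, collapse = ", "))
  mets <- as.character(unlist(x$metabolites))
  sources <- as.character(unlist(x$sources))
  reactions <- lapply(x$reactions, function(r) {
    if (is.null(r$id) || is.null(r$substrate) || is.null(r$product) ||
        is.null(r$genes)) {
      stop("reaction entry missing id/substrate/product/genes")
    }
    genes <- lapply(r$genes, function(alt) as.character(unlist(alt)))
    if (length(genes) == 0 || any(lengths(genes) == 0)) {
      stop("reaction '", r$id, "' has an empty gene requirement")
    }
    list(id = as.character(r$id), substrate = as.character(r$substrate),
         product = as.character(r$product), genes = genes)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  products <- vapply(x$products, function(p) as.character(p)[1], character(1))

  if (anyDuplicated(mets)) stop("duplicate metabolite ids")
  if (anyDuplicated(names(reactions))) stop("duplicate reaction ids")
  bad <- setdiff(sources, mets)
  if (length(bad)) stop("source(s) not declared as metabolites: ",
                        paste(bad, collapse = ", "))
  for (r in reactions) {
    if (!(r$substrate %in% mets))
      stop("reaction '", r$id, "' cites undeclared metabolite '",
           r$substrate, "'")
    if (!(r$product %in% mets))
      stop("reaction '", r$id, "' cites undeclared metabolite '",
           r$product, "'")
    if (r$substrate == r$product)
      stop("reaction '", r$id, "' is a self-loop")
  }
  for (sugar in names(products)) {
    rid <- products[[sugar]]
    if (!(rid %in% names(reactions)))
      stop("product '", sugar, "' names missing terminal reaction '", rid, "'")
    if (sugar %in% sources)
      stop("product '", sugar, "' is also a source")
  }
  net <- structure(
    list(metabolites = mets, sources = sources, reactions = reactions,
         products = products),
    class = "reference_network")
  for (sugar in names(products)) {
    if (length(enumerate_routes(net, sugar)) == 0) {
      stop("product '", sugar, "' is unreachable from any source metabolite")
    }
  }
  net
}

#' @export
print.reference_network <- function(x, ...) {
  cat("reference_network:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", length(x$products),
      "sugar products,", length(x$sources), "sources\n")
  invisible(x)
}

#' Is a reaction's gene requirement satisfied?
#'
#' OR over isoenzyme alternatives, AND within each alternative.
#'
#' @param reaction A reaction entry of a [load_network()] object.
#' @param genome_row Named 0/1 vector of gene-family presence for one genome.
#' @return Logical scalar.
#' @export
reaction_present <- function(reaction, genome_row) {
  req <- unique(unlist(reaction$genes))
  miss <- setdiff(req, names(genome_row))
  if (length(miss)) {
    stop("reaction '", reaction$id, "' requires family id(s) absent from ",
         "the presence matrix: ", paste(miss, collapse = ", "))
  }
  any(vapply(reaction$genes, function(alt) all(genome_row[alt] == 1),
             logical(1)))
}

# All simple (cycle-free in metabolite space) reaction routes from any source
# metabolite to the sugar's product metabolite, as character vectors of
# reaction ids. Exhaustive DFS; the reference networks in scope have tens of
# reactions, so a configurable depth cap keeps this safe.
enumerate_routes <- function(network, sugar_id, max_depth = 15L) {
  if (!(sugar_id %in% names(network$products))) {
    stop("unknown sugar product: ", sugar_id)
  }
  terminal <- network$reactions[[network$products[[sugar_id]]]]
  target_met <- terminal$product
  by_substrate <- split(seq_along(network$reactions),
                        vapply(network$reactions, `[[`, character(1),
                               "substrate"))
  routes <- list()
  walk <- function(met, visited, path) {
    if (met == target_met) {
      routes[[length(routes) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) >= max_depth) return(invisible())
    for (i in by_substrate[[met]]) {
      r <- network$reactions[[i]]
      if (r$product %in% visited) next
      walk(r$product, c(visited, r$product), c(path, r$id))
    }
    invisible()
  }
  for (src in network$sources) {
    walk(src, src, character(0))
  }
  # a route must end with a reaction producing the sugar metabolite; routes
  # through the target are cut at the target by construction
  routes
}

#' Network completeness of a sugar pathway in one genome
#'
#' Completeness is the maximum, over all simple reaction routes from any
#' source metabolite to the sugar, of the fraction of route reactions whose
#' gene requirement is satisfied in the genome.
#'
#' @param network A [load_network()] object.
#' @param sugar_id A sugar product id declared in the network.
#' @param genome_row Named 0/1 vector of gene-family presence.
#' @param max_depth Maximum route length considered. Default 15.
#' @return Fraction in [0, 1].
#' @export
pathway_completeness <- function(network, sugar_id, genome_row,
                                 max_depth = 15L) {
  routes <- enumerate_routes(network, sugar_id, max_depth)
  if (length(routes) == 0) stop("no route to sugar '", sugar_id, "'")
  present <- vapply(network$reactions,
                    function(r) reaction_present(r, genome_row), logical(1))
  max(vapply(routes, function(rt) mean(present[rt]), numeric(1)))
}

#' Call presence of a sugar pathway in one genome
#'
#' Detection requires two criteria simultaneously: (i) a route from central
#' carbon metabolism to the sugar at least \code{min_completeness} complete,
#' and (ii) presence of the terminal enzyme producing the sugar.
#'
#' @inheritParams pathway_completeness
#' @param min_completeness Completeness threshold. Default 0.75.
#' @param genome_id Optional genome label attached to the result.
#' @return One-row data frame: \code{genome_id}, \code{sugar_id},
#'   \code{completeness}, \code{terminal_present}, \code{detected}.
#' @export
call_pathway <- function(network, sugar_id, genome_row,
                         min_completeness = 0.75, genome_id = NA_character_,
                         max_depth = 15L) {
  comp <- pathway_completeness(network, sugar_id, genome_row, max_depth)
  terminal <- network$reactions[[network$products[[sugar_id]]]]
  term_ok <- reaction_present(terminal, genome_row)
  data.frame(genome_id = genome_id, sugar_id = sugar_id, completeness = comp,
             terminal_present = term_ok,
             detected = comp >= min_completeness && term_ok,
             stringsAsFactors = FALSE)
}

#' Call all sugar pathways for all genomes of a presence matrix
#'
#' @param network A [load_network()] object.
#' @param matrix Binary presence matrix (genomes x families).
#' @param min_completeness Completeness threshold. Default 0.75.
#' @param max_depth Maximum route length considered. Default 15.
#' @return Data frame of pathway calls, one row per genome and sugar.
#' @export
call_pathways <- function(network, matrix, min_completeness = 0.75,
                          max_depth = 15L) {
  sugars <- names(network$products)
  out <- vector("list", nrow(matrix) * length(sugars))
  k <- 0L
  for (g in rownames(matrix)) {
    row <- matrix[g, ]
    for (s in sugars) {
      k <- k + 1L
      out[[k]] <- call_pathway(network, s, row, min_completeness, g, max_depth)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify nucleotide-sugars as core, accessory or absent
#'
#' A sugar's prevalence is the fraction of genomes in which its pathway was
#' detected. Sugars detected in strictly more than \code{core_min_fraction}
#' of the genomes are core; other detected sugars are accessory; undetected
#' sugars are absent. Note the strict inequality, unlike the inclusive
#' gene-level rule of [classify_gene_prevalence()].
#'
#' @param calls Pathway-call table from [call_pathways()].
#' @param core_min_fraction Core threshold, exclusive. Default 0.9.
#' @return Data frame with columns \code{sugar_id}, \code{prevalence},
#'   \code{label}.
#' @export
classify_sugar_prevalence <- function(calls, core_min_fraction = 0.9) {
  prev <- tapply(calls$detected, calls$sugar_id, mean)
  sugars <- names(prev)
  prev <- as.numeric(prev)
  label <- ifelse(prev > core_min_fraction, "core",
                  ifelse(prev > 0, "accessory", "absent"))
  out <- data.frame(sugar_id = sugars, prevalence = prev, label = label,
                    stringsAsFactors = FALSE)
  out[order(out$sugar_id), , drop = FALSE]
}
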