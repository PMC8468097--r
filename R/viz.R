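#' Default display palette
#'
#' @return named character of colors for node roles (\code{seed},
#'   \code{treatment_unique}, \code{shared}), edge roles
#'   (\code{differential}, \code{background}) and pathway halos.
#' @export
defaultPalette <- function() {
    c(seed = "#ffd92f", treatment_unique = "#1f78b4", shared = "grey55",
        differential = "#e31a1c", background = "grey80",
        halo = "#b2df8a")
}

#' Remove hub (currency-like) compounds before visualization
#'
#' Nodes with more than \code{maxNeighbors} distinct adjacent nodes
#' (counting both directions, ignoring edge multiplicity) are removed
#' together with their incident edges. Such high-degree compounds are
#' typically ubiquitous co-reactants (water, ATP, ...) that condense
#' the drawing without carrying treatment-specific signal. Removal is
#' single-pass: degrees are measured on the input graph and not
#' recomputed after removal.
#'
#' @param net a [MetabolicNetwork-class].
#' @param maxNeighbors retain nodes with at most this many distinct
#'   neighbors (default 25; a node with exactly 25 is kept).
#' @return the filtered [MetabolicNetwork-class].
#' @export
filterHubs <- function(net, maxNeighbors = 25) {
    stopifnot(maxNeighbors >= 1)
    if (length(net@nodes) == 0L) return(net)
    ed <- net@edges
    neigh <- split(c(ed$product, ed$substrate),
        c(ed$substrate, ed$product))
    deg <- vapply(neigh, function(x) length(unique(x)), integer(1))
    hubs <- names(deg)[deg > maxNeighbors]
    keepEdge <- !(ed$substrate %in% hubs) & !(ed$product %in% hubs)
    ed2 <- ed[keepEdge, , drop = FALSE]
    rownames(ed2) <- NULL
    new("MetabolicNetwork",
        nodes = setdiff(net@nodes, hubs),
        edges = ed2, scopeLabel = net@scopeLabel,
        unmatchedEcs = net@unmatchedEcs)
}

#' Assign display roles to nodes and edges
#'
#' Node roles: \code{seed} for predicted environmental resources
#' (members of the proxy), \code{treatment_unique} for compounds
#' producible only in this treatment, \code{shared} otherwise. A
#' compound in both the proxy and the unique set is shown as a seed
#' (logged via message). Edge role is \code{differential} when any
#' witness EC of the edge is differentially abundant.
#'
#' @param net a [MetabolicNetwork-class].
#' @param proxy an [EnvironmentalProxy-class].
#' @param unique character vector of treatment-unique compounds.
#' @param differentialEcs character vector of differential ECs.
#' @return list with \code{nodeRoles} (named character over the
#'   network's nodes) and \code{edgeRoles} (character per edge row).
#' @export
assignRoles <- function(net, proxy, unique, differentialEcs) {
    nodes <- net@nodes
    roles <- stats::setNames(rep("shared", length(nodes)), nodes)
    roles[nodes %in% unique] <- "treatment_unique"
    both <- intersect(intersect(nodes, unique), proxy@compounds)
    if (length(both))
        message(sprintf("%d compound(s) both seed and treatment-unique; shown as seed: %s",
            length(both), paste(utils::head(both, 5), collapse = ", ")))
    roles[nodes %in% proxy@compounds] <- "seed"
    edgeRoles <- vapply(net@edges$ecs,
        function(e) if (any(e %in% differentialEcs)) "differential"
            else "background", character(1))
    list(nodeRoles = roles, edgeRoles = unname(edgeRoles))
}

#' Force-directed layout of a metabolite graph
#'
#' Positions nodes with the Fruchterman-Reingold algorithm in 2 or 3
#' dimensions, starting from a seeded uniform random placement, so the
#' layout is deterministic for a fixed \code{rngSeed}. With
#' \code{iterations = 0} the initial placement is returned unchanged.
#'
#' @param net a [MetabolicNetwork-class].
#' @param dims 2 or 3.
#' @param iterations number of force iterations (>= 0).
#' @param rngSeed integer seed.
#' @param nodeRoles,edgeRoles,haloPathways optional role annotations
#'   (see [assignRoles()]) stored on the layout for rendering.
#' @return a [NetworkLayout-class].
#' @export
layoutNetwork <- function(net, dims = 2, iterations = 50, rngSeed = 0,
        nodeRoles = NULL, edgeRoles = NULL, haloPathways = list()) {
    stopifnot(dims %in% c(2, 3), iterations >= 0)
    n <- length(net@nodes)
    pos <- .withSeed(rngSeed, {
        init <- matrix(stats::runif(n * dims, -1, 1), ncol = dims)
        if (iterations > 0 && n > 0) {
            igraph::layout_with_fr(.asIgraph(net), coords = init,
                niter = iterations, dim = dims)
        } else init
    })
    pos <- matrix(as.numeric(pos), ncol = dims)
    rownames(pos) <- net@nodes
    colnames(pos) <- c("x", "y", "z")[seq_len(dims)]
    if (is.null(nodeRoles))
        nodeRoles <- stats::setNames(rep("shared", n), net@nodes)
    if (is.null(edgeRoles))
        edgeRoles <- rep("background", nrow(net@edges))
    new("NetworkLayout", positions = pos, nodeRoles = nodeRoles,
        edgeRoles = edgeRoles, haloPathways = haloPathways,
        rngSeed = rngSeed, iterations = iterations)
}

# JSON-serializable view of a laid-out (sub)network
.layoutExport <- function(layout, net, nodes = net@nodes) {
    keep <- net@edges$substrate %in% nodes & net@edges$product %in% nodes
    ed <- net@edges[keep, , drop = FALSE]
    pos <- layout@positions[nodes, , drop = FALSE]
    list(
        nodes = lapply(seq_along(nodes), function(i) {
            id <- nodes[i]
            c(list(id = id),
              as.list(round(pos[i, ], 6)),
              list(role = unname(layout@nodeRoles[id]),
                halo_pathways = as.list(
                    layout@haloPathways[[id]] %||% character(0))))
        }),
        edges = lapply(which(keep), function(i) {
            list(substrate = net@edges$substrate[i],
                product = net@edges$product[i],
                role = layout@edgeRoles[i],
                reactions = as.list(net@edges$reactions[[i]]),
                ecs = as.list(net@edges$ecs[[i]]))
        }))
}

#' Render a network layout to image and coordinate exports
#'
#' Writes a 2-D raster (PNG) of the laid-out network -- edges colored
#' by differential status, nodes by role, enriched-pathway halos drawn
#' as wider background circles -- and a JSON coordinate/role export of
#' the same (2-D or 3-D) layout that any plotting front-end can
#' consume. An empty network produces a placeholder image with a
#' warning note rather than an error.
#'
#' @param layout a [NetworkLayout-class].
#' @param net the [MetabolicNetwork-class] the layout was computed on.
#' @param imagePath PNG output path.
#' @param exportPath JSON output path.
#' @param palette named colors, see [defaultPalette()].
#' @return character(2) of written paths, invisibly.
#' @export
renderNetwork <- function(layout, net, imagePath, exportPath,
        palette = defaultPalette()) {
    jsonlite::write_json(.layoutExport(layout, net), exportPath,
        auto_unbox = TRUE, digits = NA)
    grDevices::png(imagePath, width = 1400, height = 1400, res = 130)
    on.exit(grDevices::dev.off())
    if (length(net@nodes) == 0L) {
        graphics::plot.new()
        graphics::text(0.5, 0.5, "empty network (no edges to draw)")
        return(invisible(c(imagePath, exportPath)))
    }
    pos <- layout@positions[, 1:2, drop = FALSE]
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::plot(pos, type = "n", axes = FALSE, xlab = "", ylab = "",
        main = sprintf("%s expanded network", net@scopeLabel))
    ed <- net@edges
    if (nrow(ed)) {
        bg <- layout@edgeRoles != "differential"
        graphics::segments(pos[ed$substrate[bg], 1], pos[ed$substrate[bg], 2],
            pos[ed$product[bg], 1], pos[ed$product[bg], 2],
            col = palette[["background"]], lwd = 0.5)
        df <- !bg
        graphics::segments(pos[ed$substrate[df], 1], pos[ed$substrate[df], 2],
            pos[ed$product[df], 1], pos[ed$product[df], 2],
            col = palette[["differential"]], lwd = 1.2)
    }
    haloed <- names(layout@haloPathways)[lengths(layout@haloPathways) > 0]
    haloed <- intersect(haloed, rownames(pos))
    if (length(haloed))
        graphics::points(pos[haloed, , drop = FALSE], pch = 19, cex = 2.4,
            col = palette[["halo"]])
    graphics::points(pos, pch = 19, cex = 0.9,
        col = palette[layout@nodeRoles[rownames(pos)]])
    invisible(c(imagePath, exportPath))
}

# file-name-safe pathway label (spaces and odd characters -> "_")
.sanitizePathway <- function(x) gsub("[^A-Za-z0-9,._-]", "_", x)

#' Export per-pathway sub-graphs for enriched pathways
#'
#' For each enriched pathway (in the given order) the induced sub-graph
#' over its member compounds is written as a JSON coordinate/role
#' export named \code{3D_network_<label>_<i>_<pathway>.json} with i
#' running 0..k-1.
#'
#' @param layout a [NetworkLayout-class].
#' @param net the laid-out [MetabolicNetwork-class].
#' @param enrichedPathways character vector of enriched pathway names,
#'   in output order.
#' @param pathwayMap named list compound -> pathway names.
#' @param dir output directory.
#' @param label treatment display label used in file names.
#' @return character vector of written paths, invisibly.
#' @export
exportPathwaySubgraphs <- function(layout, net, enrichedPathways,
        pathwayMap, dir, label) {
    paths <- character(0)
    for (i in seq_along(enrichedPathways)) {
        p <- enrichedPathways[i]
        members <- names(pathwayMap)[vapply(pathwayMap,
            function(x) p %in% x, logical(1))]
        nodes <- intersect(net@nodes, members)
        f <- file.path(dir, sprintf("3D_network_%s_%d_%s.json",
            label, i - 1L, .sanitizePathway(p)))
        jsonlite::write_json(
            c(list(pathway = p), .layoutExport(layout, net, nodes)),
            f, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, f)
    }
    invisible(paths)
}
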