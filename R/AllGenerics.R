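#' Accessors for dualOCCF containers
#'
#' Small accessor generics for the package's S4 containers: entity
#' identifiers, the sparse positive-indicator matrix, the similarity
#' matrix and its degree vector, the factor matrices and the objective
#' trace, and cluster membership.
#'
#' @param object a dualOCCF S4 object.
#' @return The corresponding component (see the class documentation).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chemIds", function(object) standardGeneric("chemIds"))
#' @rdname accessors
#' @export
setGeneric("protIds", function(object) standardGeneric("protIds"))
#' @rdname accessors
#' @export
setGeneric("interactionPairs", function(object)
    standardGeneric("interactionPairs"))
#' @rdname accessors
#' @export
setGeneric("positiveMatrix", function(object)
    standardGeneric("positiveMatrix"))
#' @rdname accessors
#' @export
setGeneric("simIds", function(object) standardGeneric("simIds"))
#' @rdname accessors
#' @export
setGeneric("simMatrix", function(object) standardGeneric("simMatrix"))
#' @rdname accessors
#' @export
setGeneric("degreeVector", function(object) standardGeneric("degreeVector"))
#' @rdname accessors
#' @export
setGeneric("factorU", function(object) standardGeneric("factorU"))
#' @rdname accessors
#' @export
setGeneric("factorV", function(object) standardGeneric("factorV"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object)
    standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
setMethod("chemIds", "InteractionTable", function(object) object@chemIds)
#' @rdname accessors
setMethod("protIds", "InteractionTable", function(object) object@protIds)
#' @rdname accessors
setMethod("interactionPairs", "InteractionTable",
          function(object) object@pairs)
#' @rdname accessors
setMethod("positiveMatrix", "InteractionTable",
          function(object) object@positives)
#' @rdname accessors
setMethod("simIds", "SimilarityMatrix", function(object) object@ids)
#' @rdname accessors
setMethod("simMatrix", "SimilarityMatrix", function(object) object@sim)
#' @rdname accessors
setMethod("degreeVector", "SimilarityMatrix", function(object)
    setNames(Matrix::rowSums(object@sim), object@ids))
#' @rdname accessors
setMethod("factorU", "FactorModel", function(object) object@U)
#' @rdname accessors
setMethod("factorV", "FactorModel", function(object) object@V)
#' @rdname accessors
setMethod("objectiveTrace", "FactorModel",
          function(object) object@objectiveTrace)
#' @rdname accessors
setMethod("membership", "ClusterSet", function(object)
    setNames(object@membership, object@nodes))
#' @rdname accessors
setMethod("clusters", "ClusterSet", function(object)
    split(object@nodes, object@membership))
#' @rdname accessors
setMethod("networkEdges", "ProfileNetwork", function(object) {
    e <- object@edges
    if (nrow(e)) {
        e$idA <- object@nodes[e$a]
        e$idB <- object@nodes[e$b]
    } else {
        e$idA <- character(0)
        e$idB <- character(0)
    }
    e
})

setMethod("show", "InteractionTable", function(object) {
    tab <- table(factor(object@pairs$label,
                        levels = c("active", "inactive", "ambiguous")))
    cat(sprintf("InteractionTable: %d chemicals x %d proteins\n",
                length(object@chemIds), length(object@protIds)))
    cat(sprintf("  pairs: %d active, %d inactive, %d ambiguous\n",
                tab["active"], tab["inactive"], tab["ambiguous"]))
})

setMethod("show", "SimilarityMatrix", function(object) {
    nnz <- length(object@sim@x)
    cat(sprintf(
        "SimilarityMatrix: %d entities, %d stored entries (%.4f%% dense)\n",
        length(object@ids), nnz,
        100 * nnz / max(1, length(object@ids)^2)))
})

setMethod("show", "FactorModel", function(object) {
    cat(sprintf("FactorModel: U %d x %d, V %d x %d\n",
                nrow(object@U), ncol(object@U),
                nrow(object@V), ncol(object@V)))
    if (length(object@objectiveTrace))
        cat(sprintf("  objective: %.6g -> %.6g (%d recorded values)\n",
                    object@objectiveTrace[1],
                    object@objectiveTrace[length(object@objectiveTrace)],
                    length(object@objectiveTrace)))
})

setMethod("show", "OccfConfig", function(object) {
    cat(sprintf(paste0(
        "OccfConfig: pWt=%g pImp=%g pReg=%g pChem=%g pProt=%g ",
        "rank=%d nIter=%d seed=%d\n"),
        object@pWt, object@pImp, object@pReg, object@pChem, object@pProt,
        object@rank, object@nIter, object@seed))
})

setMethod("show", "ScoreCalibration", function(object) {
    cat(sprintf(
        "ScoreCalibration: w1=%.4f, inflation ratio w2/w1=%.4f, %d bins\n",
        object@w1, object@inflationRatio, length(object@breaks)))
})

setMethod("show", "ClusterSet", function(object) {
    cat(sprintf("ClusterSet: %d nodes in %d clusters%s\n",
                length(object@nodes),
                if (length(object@membership)) max(object@membership) else 0L,
                if (isTRUE(object@converged)) "" else " (not converged)"))
})

setMethod("show", "ProfileNetwork", function(object) {
    cat(sprintf("ProfileNetwork: %d drugs, %d edges (%d structurally novel)\n",
                length(object@nodes), nrow(object@edges),
                sum(object@edges$structuralNovel)))
})

setMethod("show", "BenchmarkReport", function(object) {
    cat(sprintf(
        "BenchmarkReport: %d held-out pairs, %d folds, TPR@%d = %.4f\n",
        nrow(object@results), object@nFolds, object@cutoff,
        mean(object@results$rank <= object@cutoff)))
})
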