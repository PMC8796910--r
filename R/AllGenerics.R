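#' Accessors for demographic objects
#'
#' Column accessors for [LifeTable-class] objects and slot accessors for
#' [CohortCounts-class] and [GrowthParams-class]. `lx`, `dx`, `qx`, `Lx`,
#' `Tx` are on the radix scale; `ex` is in class-width units (multiply by
#' `classWidth()` for months).
#'
#' @param object A package object.
#' @return The requested column or slot value.
#' @name accessors
#' @aliases lx dx qx Lx Tx ex radix classWidth aliveCounts sexLabel
#'   growthConstants
#' @examples
#' lt <- buildLifeTable(CohortCounts(c(100, 50, 25), sex = "female"))
#' lx(lt)
#' ex(lt) * classWidth(lt)   # life expectancy in months
NULL

#' @rdname accessors
#' @export
setGeneric("lx", function(object) standardGeneric("lx"))
#' @rdname accessors
#' @export
setGeneric("dx", function(object) standardGeneric("dx"))
#' @rdname accessors
#' @export
setGeneric("qx", function(object) standardGeneric("qx"))
#' @rdname accessors
#' @export
setGeneric("Lx", function(object) standardGeneric("Lx"))
#' @rdname accessors
#' @export
setGeneric("Tx", function(object) standardGeneric("Tx"))
#' @rdname accessors
#' @export
setGeneric("ex", function(object) standardGeneric("ex"))
#' @rdname accessors
#' @export
setGeneric("radix", function(object) standardGeneric("radix"))
#' @rdname accessors
#' @export
setGeneric("classWidth", function(object) standardGeneric("classWidth"))
#' @rdname accessors
#' @export
setGeneric("aliveCounts", function(object) standardGeneric("aliveCounts"))
#' @rdname accessors
#' @export
setGeneric("sexLabel", function(object) standardGeneric("sexLabel"))
#' @rdname accessors
#' @export
setGeneric("growthConstants",
           function(object) standardGeneric("growthConstants"))

#' @rdname accessors
setMethod("lx", "LifeTable", function(object) object@table$lx)
#' @rdname accessors
setMethod("dx", "LifeTable", function(object) object@table$dx)
#' @rdname accessors
setMethod("qx", "LifeTable", function(object) object@table$qx)
#' @rdname accessors
setMethod("Lx", "LifeTable", function(object) object@table$Lx)
#' @rdname accessors
setMethod("Tx", "LifeTable", function(object) object@table$Tx)
#' @rdname accessors
setMethod("ex", "LifeTable", function(object) object@table$ex)
#' @rdname accessors
setMethod("radix", "LifeTable", function(object) object@radix)
#' @rdname accessors
setMethod("classWidth", "LifeTable", function(object) object@classWidth)
#' @rdname accessors
setMethod("classWidth", "CohortCounts", function(object) object@classWidth)
#' @rdname accessors
setMethod("aliveCounts", "CohortCounts", function(object) object@alive)
#' @rdname accessors
setMethod("sexLabel", "CohortCounts", function(object) object@sex)
#' @rdname accessors
setMethod("sexLabel", "LifeTable", function(object) object@sex)
#' @rdname accessors
setMethod("growthConstants", "GrowthParams",
          function(object) c(a = object@a, b = object@b))
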