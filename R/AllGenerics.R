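#' @rdname ChannelStack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ChannelStack-accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname ChannelStack-accessors
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))

#' @rdname ChannelStack-accessors
#' @export
setGeneric("planeSpacing", function(x) standardGeneric("planeSpacing"))

#' @rdname maxIntensityProjection
#' @export
setGeneric("maxIntensityProjection",
           function(x, ...) standardGeneric("maxIntensityProjection"))

#' @rdname Projection-accessors
#' @export
setGeneric("imageAreaPx", function(x) standardGeneric("imageAreaPx"))

#' @rdname SegmentationMask-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname SegmentationMask-accessors
#' @export
setGeneric("minObjectSize", function(x) standardGeneric("minObjectSize"))

#' @rdname areaFraction
#' @export
setGeneric("areaFraction", function(x) standardGeneric("areaFraction"))

#' @rdname InfluenceZone-accessors
#' @export
setGeneric("ringPixels", function(x) standardGeneric("ringPixels"))

#' @rdname InfluenceZone-accessors
#' @export
setGeneric("borderClipped", function(x) standardGeneric("borderClipped"))

#' @rdname MergedClassifier-accessors
#' @export
setGeneric("activityGroups", function(x) standardGeneric("activityGroups"))

#' @rdname MergedClassifier-accessors
#' @export
setGeneric("decisionBoundaries",
           function(x) standardGeneric("decisionBoundaries"))
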