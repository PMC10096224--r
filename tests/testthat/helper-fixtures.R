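# Small fixtures built in code.

# Linear chain: uptake A (<= 10) -> convert -> export B.
chainModel <- function(uptakeCap = 10) {
  newMetabolicNetwork(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("up", "conv", "out"),
                           lower_bound = 0,
                           upper_bound = c(uptakeCap, 1000, 1000)),
    stoichiometry = list(up = c(A = 1), conv = c(A = -1, B = 1),
                         out = c(B = -1)))
}

# A metabolite no reaction can balance, with forced nonzero production.
forcedImbalanceModel <- function() {
  newMetabolicNetwork(
    metabolites = data.frame(id = c("A", "X")),
    reactions = data.frame(id = c("makeA", "makeX"),
                           lower_bound = c(0, 1),
                           upper_bound = c(5, 5)),
    stoichiometry = list(makeA = c(A = 1, X = 1), makeX = c(A = -1, X = 1)))
}

# Minimal SBML Level 3 FBC document, two reactions with gene products.
tinySBML <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
'<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
'level="3" version="1" fbc:required="false">\n',
'<model id="tiny" fbc:strict="true">\n',
'<listOfParameters>\n',
'<parameter id="lb0" value="0" constant="true"/>\n',
'<parameter id="ub10" value="10" constant="true"/>\n',
'<parameter id="ubBig" value="99999999" constant="true"/>\n',
'</listOfParameters>\n',
'<listOfCompartments><compartment id="c" constant="true"/>',
'</listOfCompartments>\n',
'<listOfSpecies>\n',
'<species id="A" compartment="c" boundaryCondition="false" ',
'hasOnlySubstanceUnits="false" constant="false"/>\n',
'<species id="B" compartment="c" boundaryCondition="true" ',
'hasOnlySubstanceUnits="false" constant="false"/>\n',
'</listOfSpecies>\n',
'<listOfReactions>\n',
'<reaction id="up" reversible="false" fast="false" ',
'fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">\n',
'<listOfProducts><speciesReference species="A" stoichiometry="1" ',
'constant="true"/></listOfProducts>\n',
'</reaction>\n',
'<reaction id="conv" reversible="false" fast="false" ',
'fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubBig">\n',
'<listOfReactants><speciesReference species="A" stoichiometry="1" ',
'constant="true"/></listOfReactants>\n',
'<listOfProducts><speciesReference species="B" stoichiometry="2" ',
'constant="true"/></listOfProducts>\n',
'<fbc:geneProductAssociation><fbc:and>\n',
'<fbc:geneProductRef fbc:geneProduct="gene1"/>\n',
'<fbc:geneProductRef fbc:geneProduct="gene2"/>\n',
'</fbc:and></fbc:geneProductAssociation>\n',
'</reaction>\n',
'</listOfReactions>\n',
'</model>\n</sbml>\n')
}
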