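Package: ces1pbpk
Title: Semi-Physiological Pharmacokinetic Simulation of CES1 Substrates in
    Liver Cirrhosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-physiologically based pharmacokinetic (semi-PBPK)
    simulator for drugs hydrolysed by hepatic carboxylesterase 1 (CES1) and
    their active metabolites.  The model couples gastrointestinal transit and
    absorption, a well-stirred liver with pathway-resolved intrinsic
    clearance and in-situ metabolite formation, a perfusion-limited kidney,
    and a systemic compartment with optional peripheral exchange.  Healthy
    parameter sets are translated to Child-Pugh A/B/C liver-cirrhosis
    physiology through scaling rules for enzyme content, functional liver
    volume, plasma protein binding, glomerular filtration and intestinal
    permeability.  Includes a virtual-population Monte Carlo engine,
    non-compartmental summaries with cirrhosis-to-healthy exposure ratios,
    and one-at-a-time sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
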