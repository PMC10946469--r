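# ClinGen copy-number-LOSS rubric: section-based point system whose summed
# score maps to a five-tier verdict (>= 0.99 pathogenic; 0.90-0.98 likely
# pathogenic; -0.89-0.89 uncertain; -0.98 - -0.90 likely benign;
# <= -0.99 benign). default_points is the suggested value for each
# criterion; sections 2, 4 and 5 are evidence-strength judgements, so every
# assessment may override points within [min_points, max_points]. At most
# one criterion may be selected per section.
section,criterion_id,default_points,min_points,max_points,description
1,1A,0,0,0,Contains protein-coding or other known functionally important elements
1,1B,-0.6,-0.6,-0.6,Does NOT contain protein-coding or any known functionally important elements
2,2A,1,1,1,Complete overlap of an established haploinsufficiency (HI) gene or genomic region
2,2B,0,0,0,Partial overlap of an established HI genomic region not including known causative genes
2,2C,-1,-1,0,Partial overlap with the 5' end of an established HI gene
2,2D,-1,-1,0,Partial overlap with the 3' end of an established HI gene
2,2E,0,-1,0.9,Both breakpoints within the same HI gene; PVS1-style loss-of-function evaluation
2,2F,-1,-1,-1,Completely contained within an established benign CNV region
2,2G,0,0,0,Overlaps an established benign CNV region but includes additional material
2,2H,0.15,0,0.15,Two or more HI predictors suggest at least one gene in the interval is HI
3,3A,0,0,0,Interval spans 0-24 protein-coding genes
3,3B,0.45,0.45,0.45,Interval spans 25-34 protein-coding genes
3,3C,0.9,0.9,0.9,Interval spans 35 or more protein-coding genes
4,4A,0.3,0,0.45,Reported proband with a highly specific and consistent phenotype
4,4B,0.3,0,0.45,Reported proband with a consistent but nonspecific phenotype
4,4C,0,0,0.45,Reported proband with a phenotype of unknown or inconsistent relevance
4,4D,0,-0.3,0,Reported proband without relevant phenotype information
4,4E,0.1,0,0.3,Reported case with unknown availability of phenotype information
4,4F,-0.45,-0.45,0,Overlap observed in general-population controls (common)
4,4G,-0.3,-0.45,0,Overlap observed in general-population controls (rare)
4,4H,-0.15,-0.3,0,Case-control data show no statistical enrichment
4,4L,0.45,0,0.45,Statistically significant case-control enrichment
4,4M,-0.9,-1,0,Statistically significant depletion in cases
4,4N,-0.9,-1,0,Overlap with a common population variant of comparable size
4,4O,-1,-1,0,Overlap refuted by curated benign assessment
5,5A,0.45,0,0.45,Observed de novo in the proband (confirmed parental testing)
5,5B,0.3,0,0.45,Observed de novo (assumed; parental testing incomplete)
5,5C,0.15,0,0.3,Segregates with a consistent phenotype in the family
5,5D,0.3,0,0.45,Segregation among multiple affected family members
5,5E,0.1,0,0.15,Inherited from an affected parent
5,5F,-0.45,-0.45,0,Inherited from an apparently unaffected parent
5,5G,0,0,0,Inheritance information is unavailable or uninformative
5,5H,0.3,0,0.3,Observations inconsistent with Mendelian expectation
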