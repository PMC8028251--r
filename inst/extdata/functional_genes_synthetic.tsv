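func_gene	substrate_group
cbhA	cellulose
cbhB	cellulose
cel5A	cellulose
cel6A	cellulose
cel9A	cellulose
cel48S	cellulose
celB	cellulose
celC	cellulose
eglA	cellulose
eglB	cellulose
cenA	cellulose
cmcA	cellulose
xynA	hemicellulose
xynB	hemicellulose
xyn10A	hemicellulose
xyn11B	hemicellulose
xsa	hemicellulose
axeA	hemicellulose
abfA	hemicellulose
abnA	hemicellulose
manB	hemicellulose
aguA	hemicellulose
arfB	hemicellulose
xylS	hemicellulose
lacA	lignin
lacB	lignin
cotA	lignin
dypB	lignin
ligA	lignin
ligB	lignin
mnp1	lignin
lip1	lignin
vanA	lignin
pcaG	lignin
bglA	cello-oligosaccharides
bglB	cello-oligosaccharides
bglX	cello-oligosaccharides
cbpA	cello-oligosaccharides
cepA	cello-oligosaccharides
celF	cello-oligosaccharides
ascB	cello-oligosaccharides
chbF	cello-oligosaccharides
ydjC	cello-oligosaccharides
bglH	cello-oligosaccharides
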