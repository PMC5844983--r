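pathway_id	pathway_name	metabolite_id
gpl	Glycerophospholipid-like (synthetic toy)	choline
gpl	Glycerophospholipid-like (synthetic toy)	phosphocholine
gpl	Glycerophospholipid-like (synthetic toy)	cdp_choline
gpl	Glycerophospholipid-like (synthetic toy)	pc
gpl	Glycerophospholipid-like (synthetic toy)	lyso_pc
gpl	Glycerophospholipid-like (synthetic toy)	glycerophosphocholine
gpl	Glycerophospholipid-like (synthetic toy)	pe
gpl	Glycerophospholipid-like (synthetic toy)	ethanolamine
gpl	Glycerophospholipid-like (synthetic toy)	phosphoethanolamine
gpl	Glycerophospholipid-like (synthetic toy)	cdp_ethanolamine
gpl	Glycerophospholipid-like (synthetic toy)	serine_head
gpl	Glycerophospholipid-like (synthetic toy)	ps
gst	Glycine-serine-threonine-like (synthetic toy)	glycine
gst	Glycine-serine-threonine-like (synthetic toy)	sarcosine
gst	Glycine-serine-threonine-like (synthetic toy)	dimethylglycine
gst	Glycine-serine-threonine-like (synthetic toy)	betaine
gst	Glycine-serine-threonine-like (synthetic toy)	choline_gst
gst	Glycine-serine-threonine-like (synthetic toy)	serine
gst	Glycine-serine-threonine-like (synthetic toy)	threonine
gst	Glycine-serine-threonine-like (synthetic toy)	glyoxylate
gst	Glycine-serine-threonine-like (synthetic toy)	creatine
gst	Glycine-serine-threonine-like (synthetic toy)	guanidinoacetate
sph	Sphingolipid-like (synthetic toy)	serine_sph
sph	Sphingolipid-like (synthetic toy)	ketosphingosine
sph	Sphingolipid-like (synthetic toy)	sphinganine
sph	Sphingolipid-like (synthetic toy)	ceramide
sph	Sphingolipid-like (synthetic toy)	sphingomyelin
sph	Sphingolipid-like (synthetic toy)	sphingosine
sph	Sphingolipid-like (synthetic toy)	s1p
sph	Sphingolipid-like (synthetic toy)	galactosylceramide
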