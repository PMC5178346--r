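# Default stop-list: surface forms too ambiguous in free isolation-source
# text to be useful as environment annotations. One lowercase form per line.
# Curated for precision; extend or replace with --stoplist / read_stoplist().
sample
samples
culture
cultures
isolate
isolated
isolation
strain
medium
media
laboratory
collection
environment
environmental
material
source
surface
area
site
field
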