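# Checksum of the shipped metabolite fixture; loadFixture() refuses a
# silently modified file.
.fixtureChecksum <- "fa4d5a0b96522a322af581a1973cacdb"
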