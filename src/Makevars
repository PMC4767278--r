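CXXFLAGS += -O3
sigmoid_batch.o: PKG_CXXFLAGS += -ffast-math -ftree-loop-vectorize -fvect-cost-model=dynamic
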