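# The hot convolution kernels need real vectorization; the default site
# flags end with -O2 -march=nocona, so append stronger ones for this
# translation unit (compiled and run on the same machine).
.PHONY: all
all: $(SHLIB)

kernels.o: kernels.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) -O3 -march=native -funroll-loops -fopenmp-simd -c kernels.cpp -o kernels.o
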