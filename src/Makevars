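CXX_STD = CXX17
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)

all: $(SHLIB)

# hot numerical kernels need the native ISA (AVX/FMA); the default platform
# flags target a generic baseline, so compile these objects explicitly
OPTFLAGS = -O3 -march=native -funroll-loops -ftree-vectorize

unet.o: unet.cpp
	$(CXX17) $(CXX17STD) $(ALL_CPPFLAGS) $(CXX17PICFLAGS) $(OPTFLAGS) -c unet.cpp -o unet.o

morph.o: morph.cpp
	$(CXX17) $(CXX17STD) $(ALL_CPPFLAGS) $(CXX17PICFLAGS) $(OPTFLAGS) -c morph.cpp -o morph.o
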