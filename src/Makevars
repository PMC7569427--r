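# The convolution micro-kernels need full optimisation. The site Makeconf is
# read after this file and would clobber a plain assignment (its C++ flag
# sets end in -O2), so the standard-specific flag sets are force-overridden.
WANET_OPT = -O3 -funroll-loops -ffp-contract=fast -fassociative-math \
  -fno-signed-zeros -fno-trapping-math -fPIC
override CXXFLAGS = $(WANET_OPT)
override CXX11FLAGS = $(WANET_OPT)
override CXX14FLAGS = $(WANET_OPT)
override CXX17FLAGS = $(WANET_OPT)
override CXX20FLAGS = $(WANET_OPT)
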