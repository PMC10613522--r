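# -march=native is probed at compile time so unsupported toolchains fall
# back cleanly to the default ISA.
NATIVE := $(shell $(CXX) -march=native -E -x c++ /dev/null >/dev/null 2>&1 && echo -march=native)
PKG_CXXFLAGS = -O3 -funroll-loops $(NATIVE)
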