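// The training loop allocates and frees a few hundred MB of activation
// buffers per minibatch. With glibc's default mmap threshold those blocks
// are returned to the kernel on free and page-faulted back in on the next
// batch, which moves most of the runtime into system time. Raising the
// threshold keeps the blocks on the heap free-list so they are reused.

#include <Rcpp.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif

// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
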