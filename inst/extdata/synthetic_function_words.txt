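a
about
all
almost
and
are
each
even
has
have
how
if
in
is
it
more
most
much
of
on
or
over
she
some
the
then
there
they
this
to
under
was
when
which
who
will
with
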